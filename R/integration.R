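# Radiomic-transcriptomic integration: pairwise Pearson correlation maps
# between imaging features and expression, computed within a stage subset
# (pooled correlations conflate stage effects), and canonical
# correspondence analysis of the biomarker abundance table constrained by
# stage.

#' Correlate radiomic features with expression
#'
#' Pairwise Pearson correlation with two-sided t-distribution p-values,
#' computed over the overlapping samples of the requested stage subset.
#' Zero-variance columns yield `r = 0`, `p = 1`. Raw p-values are starred
#' at 0.05 (`*`) and 0.01 (`**`); an optional BH adjustment across pairs is
#' off by default.
#'
#' @param radiomic Data frame/matrix, samples x imaging features, rownames
#'   = sample ids.
#' @param expression Data frame/matrix, samples x genes, rownames = sample
#'   ids.
#' @param samples Optional sample ids defining the stage subset (default:
#'   all overlapping samples).
#' @param adjust Apply BH across pairs and star `q` instead of `p`.
#' @return Data frame of class `correlation_map`: `feature`, `gene`, `r`,
#'   `p` (and `q` when `adjust`), `stars` (`""`, `"*"`, `"**"`), `n`.
#' @export
correlate_features <- function(radiomic, expression, samples = NULL,
                               adjust = FALSE) {
  radiomic <- as.data.frame(radiomic)
  expression <- as.data.frame(expression)
  common <- intersect(rownames(radiomic), rownames(expression))
  if (!is.null(samples)) common <- intersect(common, samples)
  if (length(common) < 4) stopf("need at least 4 overlapping samples")
  X <- as.matrix(radiomic[common, , drop = FALSE])
  Y <- as.matrix(expression[common, , drop = FALSE])
  n <- length(common)
  sx <- apply(X, 2, stats::sd); sy <- apply(Y, 2, stats::sd)
  R <- matrix(0, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  okx <- sx > 0; oky <- sy > 0
  if (any(okx) && any(oky))
    R[okx, oky] <- stats::cor(X[, okx, drop = FALSE], Y[, oky, drop = FALSE])
  tstat <- R * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tstat), n - 2)
  P[!okx, ] <- 1; P[, !oky] <- 1
  P[abs(R) >= 1] <- 0
  out <- data.frame(feature = rep(rownames(R), times = ncol(R)),
                    gene = rep(colnames(R), each = nrow(R)),
                    r = as.vector(R), p = as.vector(P), n = n,
                    stringsAsFactors = FALSE)
  pstar <- out$p
  if (adjust) {
    out$q <- stats::p.adjust(out$p, method = "BH")
    pstar <- out$q
  }
  out$stars <- ifelse(pstar < 0.01, "**", ifelse(pstar < 0.05, "*", ""))
  class(out) <- c("correlation_map", "data.frame")
  out
}

#' Canonical correspondence analysis constrained by stage
#'
#' Chi-square-standardized abundance regressed on the constraints
#' (weighted by row masses), followed by singular value decomposition of
#' the fitted matrix: constrained eigenvalues are the squared singular
#' values, so a single binary constraint yields exactly one constrained
#' axis. Site scores are the linear-combination scores and species scores
#' the weighted-average scores of the constrained axes.
#'
#' @param abundance Nonnegative matrix, samples x species (e.g. linear CPM
#'   of the biomarker panel); no all-zero rows or columns.
#' @param constraints Factor or data frame of explanatory variables, one
#'   row per sample (e.g. the stage).
#' @return List of class `cca_result`: `eigenvalues` (descending),
#'   `site_scores`, `species_scores`, `total_inertia`,
#'   `constrained_inertia`, `rank`.
#' @export
cca_ordination <- function(abundance, constraints) {
  Y <- as.matrix(abundance)
  if (any(Y < 0)) stopf("abundance must be nonnegative")
  if (any(rowSums(Y) == 0)) stopf("all-zero abundance row(s)")
  if (any(colSums(Y) == 0)) stopf("all-zero abundance column(s)")
  X <- stats::model.matrix(~ ., data = as.data.frame(constraints))[, -1,
                                                                   drop = FALSE]
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); c_ <- colSums(P)
  E <- r %o% c_
  Qbar <- (P - E) / sqrt(E)
  # weighted centering + projection of Qbar onto the constraint space
  Xc <- sweep(X, 2, colSums(X * r), `-`)        # weighted column centering
  Xw <- Xc * sqrt(r)
  qrX <- qr(Xw)
  Qfit <- qr.fitted(qrX, Qbar)
  sv <- svd(Qfit)
  rank <- as.integer(sum(sv$d > 1e-12))
  axes <- if (rank > 0) paste0("CCA", seq_len(rank)) else character(0)
  ev <- sv$d[seq_len(rank)]^2
  u <- sv$u[, seq_len(rank), drop = FALSE]
  v <- sv$v[, seq_len(rank), drop = FALSE]
  site <- sweep(u, 1, sqrt(r), `/`)             # LC scores
  species <- sweep(v, 1, sqrt(c_), `/`)
  dimnames(site) <- list(rownames(Y), axes)
  dimnames(species) <- list(colnames(Y), axes)
  structure(list(eigenvalues = ev, site_scores = site,
                 species_scores = species,
                 total_inertia = sum(Qbar^2),
                 constrained_inertia = sum(ev), rank = rank),
            class = "cca_result")
}
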