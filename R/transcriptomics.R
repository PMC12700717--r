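# Expression-stage operations: CPM normalization, a vectorized Welch
# two-sample test per feature with Benjamini-Hochberg adjustment, Venn
# set logic for stage-specific features, the six-biomarker filter, and
# hypergeometric gene-set enrichment. The fold-change filter is applied on
# linear CPM group means (with the same +1 pseudocount as the log
# transform), matching a p < 0.05 AND fold change > 1.5 rule.

#' Normalize counts to log2(CPM + 1)
#'
#' @param counts Nonnegative count matrix, features x samples.
#' @return Matrix of the same shape, `log2(counts / colSums * 1e6 + 1)`.
#' @export
normalize_cpm <- function(counts) {
  if (any(counts < 0)) stopf("counts must be nonnegative")
  libs <- colSums(counts)
  if (any(libs == 0)) stopf("zero-library column(s): %s",
                            paste(colnames(counts)[libs == 0], collapse = ", "))
  log2(sweep(counts, 2, libs / 1e6, `/`) + 1)
}

# vectorized Welch t-test by row; returns p-values. Degenerate rows
# (zero variance in both groups): p = 1 if the means are equal, else 0.
welch_rows <- function(m, ia, ib) {
  na <- length(ia); nb <- length(ib)
  xa <- m[, ia, drop = FALSE]; xb <- m[, ib, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  t <- (mb - ma) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
  p
}

#' Two-group differential expression test
#'
#' Welch's unequal-variance t-test per feature on the normalized matrix,
#' with Benjamini-Hochberg adjustment across features. The DE flag requires
#' both `p < p_cutoff` and a linear fold change beyond `fc_cutoff` (in
#' either direction), the fold change being computed on linear CPM group
#' means with a +1 pseudocount.
#'
#' @param norm Normalized matrix from [normalize_cpm()].
#' @param group_a,group_b Column names (sample ids) of the two groups, at
#'   least 2 each; log2FC is reported as B versus A.
#' @param p_cutoff,fc_cutoff Flag thresholds (defaults 0.05 and 1.5).
#' @return Data frame of class `de_result`: `feature_id`, `log2fc`, `p`,
#'   `q`, `de_flag`, plus `mean_a`, `mean_b` (linear CPM).
#' @export
de_test <- function(norm, group_a, group_b, p_cutoff = 0.05,
                    fc_cutoff = 1.5) {
  ia <- match(group_a, colnames(norm)); ib <- match(group_b, colnames(norm))
  if (anyNA(ia) || anyNA(ib)) stopf("group sample ids missing from matrix")
  if (length(ia) < 2 || length(ib) < 2)
    stopf("need at least 2 samples per group")
  cpm <- 2^norm - 1
  ma <- rowMeans(cpm[, ia, drop = FALSE])
  mb <- rowMeans(cpm[, ib, drop = FALSE])
  fc <- (mb + 1) / (ma + 1)
  p <- welch_rows(norm, ia, ib)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(feature_id = rownames(norm),
                    log2fc = log2(fc), p = p, q = q,
                    de_flag = p < p_cutoff &
                      (fc > fc_cutoff | fc < 1 / fc_cutoff),
                    mean_a = ma, mean_b = mb,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

de_flags <- function(de) de$feature_id[de$de_flag]

#' Stage-specific feature sets (Venn logic)
#'
#' A feature is T2c-specific when flagged in the T2c-versus-healthy
#' comparison but not in the T3b-versus-healthy one (and symmetrically for
#' T3b); features flagged in both are shared. The all-tumor comparison is
#' recorded for the Venn report but does not subtract from specificity.
#'
#' @param de_t2c,de_t3b,de_all [de_test()] results over the same feature
#'   universe: T2c vs healthy, T3b vs healthy, all tumors vs healthy.
#' @return List: `specific_T2c`, `specific_T3b`, `shared`, and `venn`
#'   (named counts of all three flag sets and their overlaps).
#' @export
stage_specific_sets <- function(de_t2c, de_t3b, de_all = NULL) {
  if (!identical(sort(de_t2c$feature_id), sort(de_t3b$feature_id)))
    stopf("mismatched feature universes")
  if (!is.null(de_all) &&
      !identical(sort(de_t2c$feature_id), sort(de_all$feature_id)))
    stopf("mismatched feature universes")
  a <- de_flags(de_t2c); b <- de_flags(de_t3b)
  c_ <- if (is.null(de_all)) character(0) else de_flags(de_all)
  list(specific_T2c = setdiff(a, b),
       specific_T3b = setdiff(b, a),
       shared = intersect(a, b),
       venn = c(T2c_vs_H = length(a), T3b_vs_H = length(b),
                all_vs_H = length(c_),
                T2c_and_T3b = length(intersect(a, b)),
                T2c_and_all = length(intersect(a, c_)),
                T3b_and_all = length(intersect(b, c_)),
                all_three = length(Reduce(intersect, list(a, b, c_)))))
}

#' Filter a biomarker panel by the DE thresholds
#'
#' Returns the panel members passing `p < 0.05` and fold change `> 1.5`
#' in the T2c-versus-T3b comparison, with their direction of regulation.
#'
#' @param de A [de_test()] result (conventionally T3b versus T2c, so "up"
#'   means higher in T3b).
#' @param panel Feature ids to test (default the six staging biomarkers).
#' @param p_cutoff,fc_cutoff Filter thresholds.
#' @return Data frame: `feature_id`, `log2fc`, `p`, `q`, `direction`
#'   (`"up"`/`"down"`), one row per passing panel member.
#' @export
biomarker_filter <- function(de, panel = biomarker_panel()$feature_id,
                             p_cutoff = 0.05, fc_cutoff = 1.5) {
  if (!all(panel %in% de$feature_id))
    stopf("panel members missing from the DE universe: %s",
          paste(setdiff(panel, de$feature_id), collapse = ", "))
  sub <- de[de$feature_id %in% panel, ]
  fc <- 2^sub$log2fc
  pass <- sub$p < p_cutoff & (fc > fc_cutoff | fc < 1 / fc_cutoff)
  out <- sub[pass, c("feature_id", "log2fc", "p", "q")]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test of over-representation of `features`
#' in each collection entry, with BH adjustment across sets.
#'
#' @param features Character vector, the query set.
#' @param collection Named list of character vectors (e.g. [read_gmt()]).
#' @param universe Character vector containing all tested features; sets
#'   are intersected with it.
#' @return Data frame: `set`, `overlap`, `set_size`, `query_size`, `p`,
#'   `q`, sorted by `p`.
#' @export
enrich_sets <- function(features, collection, universe) {
  if (!length(universe)) stopf("empty universe")
  universe <- unique(universe)
  features <- intersect(features, universe)
  n <- length(features)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    k <- length(intersect(features, set))
    p <- if (n == 0 || !length(set)) 1 else
      stats::phyper(k - 1, length(set), length(universe) - length(set), n,
                    lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               query_size = n, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), ]
}
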