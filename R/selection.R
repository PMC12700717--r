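# Correlation-based stepwise relevance-redundancy feature selection. The
# priming feature is the one most correlated (in absolute value) with the
# 0/1-encoded class; each later step selects the candidate maximizing
# relevance minus mean absolute correlation with the retained set (the
# "most related to the class but least related to the retained" criterion).
# Independently of the selection criterion, every step logs the literal
# score "mean |r| with retained features + relevance", and the procedure
# terminates when that score drops sharply: score_t < drop_ratio *
# score_{t-1}. The feature whose score triggers the drop is not retained.

#' Selection parameters
#'
#' @param drop_ratio Relative-drop threshold in (0, 1): stop when the
#'   current step's score falls below `drop_ratio` times the previous
#'   step's.
#' @param max_features Hard cap on the number of selected features.
#' @param redundancy_sign `"minus"` (default; penalize redundancy in the
#'   selection criterion) or `"plus"` (select by the literal score itself).
#' @return List of class `selection_params`.
#' @export
selection_params <- function(drop_ratio = 0.5, max_features = 20,
                             redundancy_sign = c("minus", "plus")) {
  if (drop_ratio <= 0 || drop_ratio >= 1) stopf("drop_ratio must be in (0, 1)")
  if (max_features < 1) stopf("max_features must be >= 1")
  structure(list(drop_ratio = drop_ratio,
                 max_features = as.integer(max_features),
                 redundancy_sign = match.arg(redundancy_sign)),
            class = "selection_params")
}

#' Relevance of a feature to the class
#'
#' Absolute Pearson correlation with the 0/1-encoded class label; a
#' zero-variance feature has relevance 0.
#'
#' @param x Numeric feature values.
#' @param labels Two-level class labels (factor, character or 0/1).
#' @return Value in `[0, 1]`.
#' @export
relevance <- function(x, labels) {
  y <- encode_labels(labels)
  if (length(x) < 3) stopf("need at least 3 samples")
  abs_cor0(x, y)
}

encode_labels <- function(labels) {
  f <- as.factor(labels)
  if (nlevels(f) != 2) stopf("labels must have exactly 2 classes present")
  as.numeric(f == levels(f)[2])
}

# |cor| with zero-variance guard
abs_cor0 <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  abs(stats::cor(a, b))
}

#' Stepwise relevance-redundancy feature selection
#'
#' @param x Data frame or matrix, samples x features (named columns).
#' @param labels Two-level class labels, one per sample.
#' @param params A [selection_params()].
#' @return A list of class `selection_trace`: `selected` (ordered names),
#'   and per accepted step `score`, `relevance`, `redundancy`, `criterion`;
#'   `reason` is one of `"score_drop"`, `"max_features"`, `"exhausted"`.
#'   Ties are broken by lexicographic feature name.
#' @export
select_features <- function(x, labels, params = selection_params()) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stopf("need at least 2 features")
  if (nrow(x) < 4) stopf("need at least 4 samples")
  y <- encode_labels(labels)
  feats <- sort(colnames(x))          # lexicographic total order
  rel <- vapply(feats, function(f) abs_cor0(x[[f]], y), numeric(1))

  selected <- character(0)
  sc <- rl <- rd <- cr <- numeric(0)
  reason <- "exhausted"
  prev_score <- NA_real_
  while (length(selected) < params$max_features) {
    cand <- setdiff(feats, selected)
    if (!length(cand)) { reason <- "exhausted"; break }
    red <- vapply(cand, function(f) {
      if (!length(selected)) return(0)
      mean(vapply(selected, function(g) abs_cor0(x[[f]], x[[g]]),
                  numeric(1)))
    }, numeric(1))
    crit <- if (params$redundancy_sign == "minus") rel[cand] - red
            else rel[cand] + red
    best <- cand[order(-crit, cand)][1]   # max criterion, name breaks ties
    score <- red[[best]] + rel[[best]]    # literal stopping score
    if (length(selected) >= 1 && score < params$drop_ratio * prev_score) {
      reason <- "score_drop"
      break
    }
    selected <- c(selected, best)
    sc <- c(sc, score); rl <- c(rl, rel[[best]]); rd <- c(rd, red[[best]])
    cr <- c(cr, crit[[best]])
    prev_score <- score
    if (length(selected) >= params$max_features) {
      reason <- "max_features"
      break
    }
  }
  structure(list(selected = selected, score = sc, relevance = rl,
                 redundancy = rd, criterion = cr, reason = reason,
                 params = params),
            class = "selection_trace")
}
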