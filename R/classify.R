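# Multi-model staging evaluation. The AUC is the Mann-Whitney rank
# statistic (ties contribute one half), computed from scratch so the
# evaluation does not depend on any classifier library's ROC code. The
# evaluation protocol is R repeated stratified 70/30 train/test splits;
# the same splits are reused across feature sets and models so comparisons
# are paired. Features are z-scored with train-split statistics only.

#' Rank-based AUC
#'
#' Probability that a random positive outscores a random negative, via the
#' Mann-Whitney U statistic on midranks (ties count one half).
#'
#' @param scores Numeric classifier scores, larger = more positive.
#' @param labels Two-level labels; the second factor level is the positive
#'   class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  y <- encode_labels(labels)
  npos <- sum(y == 1); nneg <- sum(y == 0)
  r <- rank(scores)          # midranks handle ties
  (sum(r[y == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# stratified split: for each class, floor(train_frac * n) train samples
# (at least 1 train and 1 test per class)
stratified_split <- function(labels, train_frac) {
  idx_train <- integer(0)
  for (lv in levels(as.factor(labels))) {
    ii <- which(labels == lv)
    ntr <- max(1L, min(length(ii) - 1L, floor(train_frac * length(ii))))
    idx_train <- c(idx_train, sample(ii, ntr))
  }
  sort(idx_train)
}

train_score <- function(model, xtr, ytr, xte, pos_level) {
  switch(model,
    random_forest = {
      fit <- randomForest::randomForest(xtr, ytr)
      stats::predict(fit, xte, type = "prob")[, pos_level]
    },
    naive_bayes = {
      fit <- e1071::naiveBayes(xtr, ytr)
      stats::predict(fit, xte, type = "raw")[, pos_level]
    },
    svm = {
      fit <- e1071::svm(xtr, ytr, kernel = "radial")
      dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
                 "decision.values")
      # decision values are oriented toward the first class in the
      # colname "a/b"; flip when the positive class is the second
      lab <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
      if (lab[1] == pos_level) dv[, 1] else -dv[, 1]
    },
    stopf("unknown model '%s'", model))
}

#' Evaluate feature sets across models and repeated splits
#'
#' @param features Data frame, samples x features (numeric columns only),
#'   rownames = sample ids.
#' @param labels Two-level factor (e.g. T2c/T3b), one per sample; the
#'   second level is the positive class.
#' @param sets Named list of character vectors selecting columns of
#'   `features` (e.g. clinical / transcriptomic / radiomic / combined).
#' @param models Subset of `c("random_forest", "naive_bayes", "svm")`.
#' @param runs Number of repeated stratified splits (default 10).
#' @param train_frac Training fraction per class (default 0.7).
#' @param seed Seed fixing the splits and model fits.
#' @return List of class `eval_result`: `runs` (data frame with
#'   `feature_set`, `model`, `run`, `auc`) and `summary` (mean and sd of
#'   AUC per set x model).
#' @export
evaluate_models <- function(features, labels, sets,
                            models = c("random_forest", "naive_bayes",
                                       "svm"),
                            runs = 10, train_frac = 0.7, seed = 1) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("labels must have exactly 2 levels")
  if (min(table(labels)) < 3) stopf("need at least 3 samples per class")
  for (nm in names(sets))
    if (!all(sets[[nm]] %in% colnames(features)))
      stopf("set '%s' selects missing columns", nm)
  pos_level <- levels(labels)[2]
  res <- with_seed(seed, {
    splits <- lapply(seq_len(runs), function(i)
      stratified_split(labels, train_frac))
    rows <- list()
    for (run in seq_len(runs)) {
      tr <- splits[[run]]; te <- setdiff(seq_along(labels), tr)
      for (set_name in names(sets)) {
        xs <- as.matrix(features[, sets[[set_name]], drop = FALSE])
        mu <- colMeans(xs[tr, , drop = FALSE])
        sg <- apply(xs[tr, , drop = FALSE], 2, stats::sd)
        sg[sg == 0] <- 1                       # constant column guard
        z <- sweep(sweep(xs, 2, mu), 2, sg, `/`)
        for (model in models) {
          sc <- train_score(model, z[tr, , drop = FALSE], labels[tr],
                            z[te, , drop = FALSE], pos_level)
          rows[[length(rows) + 1L]] <- data.frame(
            feature_set = set_name, model = model, run = run,
            auc = auc_rank(sc, labels[te]), stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  agg_m <- stats::aggregate(auc ~ feature_set + model, res, mean)
  agg_s <- stats::aggregate(auc ~ feature_set + model, res, stats::sd)
  names(agg_m)[3] <- "mean_auc"; agg_m$sd_auc <- agg_s$auc
  structure(list(runs = res, summary = agg_m), class = "eval_result")
}
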