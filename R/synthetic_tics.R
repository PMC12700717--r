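# Destruction-replenishment kinetics: after the microbubble destruction
# flash, contrast intensity refills as I(t) = A (1 - exp(-beta t)). Group
# parameters encode increasing perfusion with stage (locally advanced tumors
# are more vascular); per-subject lognormal jitter adds realistic spread.

tic_group_params <- function(group) {
  switch(group,
         healthy = c(A = 8, beta = 0.35),
         T2c = c(A = 12, beta = 0.5),
         T3b = c(A = 16, beta = 0.8))
}

#' Generate synthetic CEUS time-intensity curves
#'
#' One refill curve per subject on a fixed grid of 40 time points, following
#' `I(t) = A (1 - exp(-beta t))` with additive Gaussian noise of standard
#' deviation `cfg$tic_noise_sd * A`. The subject's true `(A, beta)` are
#' returned for recovery testing.
#'
#' @param cfg A [study_config()].
#' @return A list with one element per subject: `subject_id`, `group`, `t`
#'   (seconds), `intensity`, `A_true`, `beta_true`.
#' @export
gen_tics <- function(cfg) {
  validate_config(cfg)
  subj <- subject_table(cfg)
  tt <- seq(0.3, 12, length.out = 40)
  with_seed(cfg$seed + 301L, {
    lapply(seq_len(nrow(subj)), function(i) {
      p <- tic_group_params(as.character(subj$group[i]))
      A <- p["A"] * stats::rlnorm(1, 0, 0.15)
      beta <- p["beta"] * stats::rlnorm(1, 0, 0.15)
      mu <- A * (1 - exp(-beta * tt))
      ii <- mu + stats::rnorm(length(tt), 0, cfg$tic_noise_sd * A)
      list(subject_id = subj$subject_id[i],
           group = as.character(subj$group[i]),
           t = tt, intensity = as.numeric(ii),
           A_true = unname(A), beta_true = unname(beta))
    })
  })
}
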