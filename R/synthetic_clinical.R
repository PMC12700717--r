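# Group-wise clinical generating moments. Tumor-stage rows reproduce the
# cohort's published summary statistics (mean +/- SD per stage); the healthy
# control row is synthetic (screening-negative values, since controls have
# no Gleason score and near-baseline PSA).
clinical_moments <- function() {
  list(
    healthy = list(age = c(64.0, 8.0), tPSA = c(1.2, 0.8),
                   fPSA_ratio = c(0.28, 0.10), trus_volume = c(28.0, 9.0),
                   psa_density = c(0.04, 0.03),
                   gleason = c("none" = 1)),
    T2c = list(age = c(70.11, 7.90), tPSA = c(42.11, 33.66),
               fPSA_ratio = c(0.12, 0.07), trus_volume = c(41.57, 20.03),
               psa_density = c(0.49, 0.58),
               gleason = c("3+3" = 2, "3+4" = 7, "4+3" = 14, ">=8" = 12)),
    T3b = list(age = c(68.46, 7.01), tPSA = c(29.88, 33.92),
               fPSA_ratio = c(0.11, 0.10), trus_volume = c(49.50, 19.86),
               psa_density = c(0.50, 0.51),
               gleason = c("3+3" = 1, "3+4" = 3, "4+3" = 5, ">=8" = 4)))
}

#' Generate a synthetic clinical table
#'
#' Draws per-subject clinical covariates (age, total PSA, free/total PSA
#' ratio, TRUS volume, PSA density) from group-specific truncated-normal
#' distributions whose tumor-stage moments match the cohort's published
#' summary table; Gleason scores are sampled from the published category
#' counts (exact multiset when the group size matches the published size,
#' proportional otherwise). Healthy-control moments are synthetic
#' screening-negative values.
#'
#' @param cfg A [study_config()].
#' @return A data frame of clinical records: `subject_id`, `group`, `age`,
#'   `tPSA`, `fPSA_ratio`, `trus_volume`, `psa_density`, `gleason` (ordered
#'   factor, `none` for controls).
#' @export
gen_clinical <- function(cfg) {
  validate_config(cfg)
  subj <- subject_table(cfg)
  mom <- clinical_moments()
  draws <- with_seed(cfg$seed + 101L, {
    lapply(levels(subj$group), function(g) {
      n <- sum(subj$group == g)
      m <- mom[[g]]
      cnt <- m$gleason
      gl <- if (g == "healthy") rep("none", n)
            else if (sum(cnt) == n) sample(rep(names(cnt), cnt))
            else sample(names(cnt), n, replace = TRUE, prob = cnt / sum(cnt))
      data.frame(
        age = rnorm_pos(n, m$age[1], m$age[2]),
        tPSA = rnorm_pos(n, m$tPSA[1], m$tPSA[2]),
        fPSA_ratio = rnorm_pos(n, m$fPSA_ratio[1], m$fPSA_ratio[2]),
        trus_volume = rnorm_pos(n, m$trus_volume[1], m$trus_volume[2]),
        psa_density = rnorm_pos(n, m$psa_density[1], m$psa_density[2]),
        gleason = gl,
        stringsAsFactors = FALSE)
    })
  })
  out <- cbind(subj, do.call(rbind, draws))
  out$gleason <- factor(out$gleason,
                        levels = c("none", "3+3", "3+4", "4+3", ">=8"),
                        ordered = TRUE)
  rownames(out) <- NULL
  out
}
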