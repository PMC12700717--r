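#' Synthetic study configuration
#'
#' Bundles every knob of the synthetic-study generator. The defaults mirror
#' the motivating cohort (22 healthy controls, 35 stage-T2c and 13 stage-T3b
#' prostate-cancer patients) and plant effects strong enough that each
#' downstream stage has signal to find: a texture contrast separating the
#' two tumor stages, stage-specific differentially expressed features at a
#' fixed log2 fold change, monotone-trend features feeding the regulatory
#' network, and a planted four-hub miRNA-target graph.
#'
#' @param n_healthy,n_T2c,n_T3b Cohort sizes per group (all >= 1).
#' @param image_size Side of the square synthetic images, in pixels; must be
#'   >= 32 and divisible by 4 (two decimation levels).
#' @param texture_contrast Dimensionless effect size separating T2c from T3b
#'   speckle texture inside the ROI; 0 means no textural signal.
#' @param de_log2fc Planted log2 fold change for differential-expression
#'   effects (biomarkers and stage-specific sets); 0 means a null generator.
#' @param n_planted_de Number of planted stage-specific DE mRNAs per stage.
#' @param nb_dispersion Negative-binomial dispersion of the count generator
#'   (variance = mu + dispersion * mu^2); must be > 0.
#' @param tic_noise_sd Gaussian noise on time-intensity curves, as a fraction
#'   of the subject's plateau intensity.
#' @param seed Integer seed; fixes every draw (bit-identical reruns).
#' @param n_mrna,n_mirna Total mRNA / miRNA features in the count matrices.
#' @param n_mirna_planted_de Planted stage-specific DE miRNAs per stage.
#' @param n_monotone_mrna Planted mRNAs with monotonically decreasing group
#'   means healthy -> T2c -> T3b (at least 9 so the regulatory network can
#'   cover nine target genes).
#' @param n_monotone_mirna Planted miRNAs with monotonically increasing group
#'   means (at least 4, the hub count of the planted network).
#' @param n_decoy_edges Low-degree decoy edges added to the planted
#'   interaction graph.
#'
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_healthy = 22, n_T2c = 35, n_T3b = 13,
                         image_size = 128, texture_contrast = 1.5,
                         de_log2fc = 1.5, n_planted_de = 40,
                         nb_dispersion = 0.1, tic_noise_sd = 0.05,
                         seed = 1L,
                         n_mrna = 2000, n_mirna = 400,
                         n_mirna_planted_de = 10,
                         n_monotone_mrna = 12, n_monotone_mirna = 6,
                         n_decoy_edges = 30) {
  cfg <- list(n_healthy = as.integer(n_healthy), n_T2c = as.integer(n_T2c),
              n_T3b = as.integer(n_T3b), image_size = as.integer(image_size),
              texture_contrast = texture_contrast, de_log2fc = de_log2fc,
              n_planted_de = as.integer(n_planted_de),
              nb_dispersion = nb_dispersion, tic_noise_sd = tic_noise_sd,
              seed = as.integer(seed),
              n_mrna = as.integer(n_mrna), n_mirna = as.integer(n_mirna),
              n_mirna_planted_de = as.integer(n_mirna_planted_de),
              n_monotone_mrna = as.integer(n_monotone_mrna),
              n_monotone_mirna = as.integer(n_monotone_mirna),
              n_decoy_edges = as.integer(n_decoy_edges))
  class(cfg) <- "study_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_healthy < 1 || cfg$n_T2c < 1 || cfg$n_T3b < 1)
    stopf("all cohort sizes must be >= 1")
  if (cfg$image_size < 32 || cfg$image_size %% 4 != 0)
    stopf("image_size must be >= 32 and divisible by 4, got %d", cfg$image_size)
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (cfg$tic_noise_sd < 0) stopf("tic_noise_sd must be >= 0")
  if (cfg$n_monotone_mrna < 9)
    stopf("n_monotone_mrna must be >= 9 (nine network target genes)")
  if (cfg$n_monotone_mirna < 4)
    stopf("n_monotone_mirna must be >= 4 (four network hubs)")
  invisible(cfg)
}

# Subject ids and the group factor, in a fixed order: healthy, T2c, T3b.
subject_table <- function(cfg) {
  n <- cfg$n_healthy + cfg$n_T2c + cfg$n_T3b
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = factor(rep(c("healthy", "T2c", "T3b"),
                       c(cfg$n_healthy, cfg$n_T2c, cfg$n_T3b)),
                   levels = c("healthy", "T2c", "T3b")),
    stringsAsFactors = FALSE)
}

#' The six staging biomarkers
#'
#' Identifiers of the three mRNA and three miRNA biomarkers separating the
#' T3b from the T2c stage, with their expected direction of regulation in
#' T3b (FZD4, RPS7, RPL29 and miR-9-3p up; miR-374c-5p and miR-6510-3p down).
#'
#' @return A data frame with columns `feature_id`, `modality`, `direction`.
#' @export
biomarker_panel <- function() {
  data.frame(
    feature_id = c("FZD4", "RPS7", "RPL29",
                   "miR-9-3p", "miR-374c-5p", "miR-6510-3p"),
    modality = c("mrna", "mrna", "mrna", "mirna", "mirna", "mirna"),
    direction = c("up", "up", "up", "up", "down", "down"),
    stringsAsFactors = FALSE)
}
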