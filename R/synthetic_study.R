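#' Simulate a complete synthetic study
#'
#' Runs every generator under the configuration's seed and returns the full
#' bundle a real study would supply: clinical table, image pairs with ROI
#' masks, time-intensity curves, mRNA/miRNA counts with the planted-effect
#' truth table, and the miRNA-target interaction edge list.
#'
#' @param cfg A [study_config()].
#' @return A list with elements `config`, `clinical`, `images`, `tics`,
#'   `expression` (list `mrna`, `mirna`, `truth`) and `interactions`.
#' @export
simulate_study <- function(cfg = study_config()) {
  validate_config(cfg)
  expr <- gen_expression(cfg)
  list(config = cfg,
       clinical = gen_clinical(cfg),
       images = gen_images(cfg),
       tics = gen_tics(cfg),
       expression = expr,
       interactions = gen_interactions(cfg, expr$truth))
}

#' Write a simulated study to disk
#'
#' Images and masks are written as 8-bit grayscale PNG (masks 0/255); the
#' time-intensity curves, counts, clinical table, truth table and edge list
#' as headered CSV/TSV; the configuration as YAML.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images"); mask_dir <- file.path(dir, "masks")
  dir.create(img_dir, showWarnings = FALSE)
  dir.create(mask_dir, showWarnings = FALSE)
  for (rec in study$images) {
    stem <- sprintf("%s_%s.png", rec$subject_id, rec$modality)
    png::writePNG(rec$image, file.path(img_dir, stem))
    png::writePNG(rec$mask * 1.0, file.path(mask_dir, stem))
  }
  tic_df <- do.call(rbind, lapply(study$tics, function(x)
    data.frame(subject_id = x$subject_id, t = x$t, intensity = x$intensity)))
  write_table10(tic_df, file.path(dir, "tics.csv"), sep = ",")
  write_table10(study$clinical, file.path(dir, "clinical.csv"), sep = ",")
  write_counts(study$expression$mrna, file.path(dir, "mrna_counts.tsv"))
  write_counts(study$expression$mirna, file.path(dir, "mirna_counts.tsv"))
  write_table10(study$expression$truth, file.path(dir, "truth.tsv"),
                sep = "\t")
  write_table10(study$interactions, file.path(dir, "interactions.tsv"),
                sep = "\t")
  cfg <- study$config; class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
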