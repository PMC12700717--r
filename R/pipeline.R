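# End-to-end driver: simulate (or load) -> extract -> perfusion -> DE/Venn
# -> selection -> integration -> classification -> regulatory network.
# Every stage is wrapped so a failure aborts with the stage's name, and all
# tabular outputs are written with fixed float formatting so a rerun with
# the same configuration and seed is byte-identical.

#' Pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param study A [study_config()] (also carries the master seed).
#' @param simulate Generate the study (`TRUE`) or load it from
#'   `input_dir`, which must follow the [write_study()] layout.
#' @param input_dir Directory of study inputs when `simulate = FALSE`.
#' @param ng,wavelet Texture extraction parameters.
#' @param modality Image modality used for texture features.
#' @param drop_ratio,max_features Stepwise-selection parameters.
#' @param p_cutoff,fc_cutoff Differential-expression thresholds.
#' @param runs,train_frac Classifier evaluation protocol.
#' @param hub_min_degree,trend_delta Regulatory-network parameters.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("radiostage_run_"),
                            study = study_config(), simulate = TRUE,
                            input_dir = NULL, ng = 32, wavelet = "haar",
                            modality = "CEUS-peak", drop_ratio = 0.5,
                            max_features = 20, p_cutoff = 0.05,
                            fc_cutoff = 1.5, runs = 10, train_frac = 0.7,
                            hub_min_degree = 2, trend_delta = 0) {
  structure(list(out_dir = out_dir, study = study, simulate = simulate,
                 input_dir = input_dir, ng = ng, wavelet = wavelet,
                 modality = modality, drop_ratio = drop_ratio,
                 max_features = max_features, p_cutoff = p_cutoff,
                 fc_cutoff = fc_cutoff, runs = runs,
                 train_frac = train_frac,
                 hub_min_degree = hub_min_degree,
                 trend_delta = trend_delta),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; the `study` sub-map is passed to
#' [study_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stopf("unknown config key(s): %s",
                         paste(bad, collapse = ", "))
  if (!is.null(raw$study)) {
    bad <- setdiff(names(raw$study), names(formals(study_config)))
    if (length(bad)) stopf("unknown study key(s): %s",
                           paste(bad, collapse = ", "))
    raw$study <- do.call(study_config, raw$study)
  }
  do.call(pipeline_config, raw)
}

load_study_inputs <- function(dir, cfg) {
  need <- c("clinical.csv", "tics.csv", "mrna_counts.tsv",
            "mirna_counts.tsv", "interactions.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stopf("missing transcriptomics/imaging inputs in '%s': %s", dir,
          paste(missing, collapse = ", "))
  clinical <- utils::read.csv(file.path(dir, "clinical.csv"),
                              stringsAsFactors = FALSE)
  clinical$group <- factor(clinical$group,
                           levels = c("healthy", "T2c", "T3b"))
  imgs <- list.files(file.path(dir, "images"), full.names = TRUE,
                     pattern = "\\.png$")
  images <- lapply(imgs, function(p) {
    stem <- sub("\\.png$", "", basename(p))
    parts <- strsplit(stem, "_", fixed = TRUE)[[1]]
    pair <- read_image_pair(p, file.path(dir, "masks", basename(p)))
    sid <- parts[1]
    list(subject_id = sid,
         group = as.character(clinical$group[match(sid,
                                                   clinical$subject_id)]),
         modality = paste(parts[-1], collapse = "_"),
         image = pair$image, mask = pair$mask)
  })
  tics <- read_tics(file.path(dir, "tics.csv"))
  grp <- clinical$group[match(vapply(tics, `[[`, character(1),
                                     "subject_id"), clinical$subject_id)]
  tics <- Map(function(tc, g) { tc$group <- as.character(g); tc },
              tics, grp)
  list(clinical = clinical, images = images, tics = tics,
       expression = list(
         mrna = read_counts(file.path(dir, "mrna_counts.tsv")),
         mirna = read_counts(file.path(dir, "mirna_counts.tsv")),
         truth = NULL),
       interactions = utils::read.delim(file.path(dir, "interactions.tsv"),
                                        stringsAsFactors = FALSE))
}

#' Run the full pipeline
#'
#' Executes simulate/load -> texture extraction -> perfusion fitting ->
#' differential expression and Venn logic -> biomarker filter -> stepwise
#' selection -> correlation/CCA integration -> classifier evaluation ->
#' regulatory network, writing each stage's tables under
#' `config$out_dir`. Any stage failure aborts with the stage name and
#' cause.
#'
#' @param config A [pipeline_config()].
#' @return The report bundle (named list of all stage results), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  scfg <- config$study

  study <- stage("simulate", {
    if (config$simulate) simulate_study(scfg)
    else {
      if (is.null(config$input_dir))
        stopf("simulate disabled and no input_dir given")
      load_study_inputs(config$input_dir, config)
    }
  })
  clinical <- study$clinical
  tumor <- clinical$subject_id[clinical$group %in% c("T2c", "T3b")]
  stage_lab <- droplevels(clinical$group[match(tumor,
                                               clinical$subject_id)])

  radiomic <- stage("extract", {
    tab <- extract_table(study$images, modality = config$modality,
                         ng = config$ng, wavelet = config$wavelet)
    write_table10(tab, file.path(config$out_dir, "radiomic_features.csv"),
                  sep = ",")
    tab
  })

  perf <- stage("perfusion", {
    tab <- perfusion_table(study$tics)
    write_table10(tab, file.path(config$out_dir, "perfusion.csv"),
                  sep = ",")
    tab
  })

  tx <- stage("transcriptomics", {
    norm <- rbind(normalize_cpm(study$expression$mrna),
                  normalize_cpm(study$expression$mirna))
    ids <- split(clinical$subject_id, clinical$group)
    de_t2c <- de_test(norm, ids$healthy, ids$T2c, config$p_cutoff,
                      config$fc_cutoff)
    de_t3b <- de_test(norm, ids$healthy, ids$T3b, config$p_cutoff,
                      config$fc_cutoff)
    de_all <- de_test(norm, ids$healthy, tumor, config$p_cutoff,
                      config$fc_cutoff)
    de_stage <- de_test(norm, ids$T2c, ids$T3b, config$p_cutoff,
                        config$fc_cutoff)
    sets <- stage_specific_sets(de_t2c, de_t3b, de_all)
    bio <- biomarker_filter(de_stage, p_cutoff = config$p_cutoff,
                            fc_cutoff = config$fc_cutoff)
    for (nm in c("de_t2c", "de_t3b", "de_all", "de_stage"))
      write_table10(get(nm), file.path(config$out_dir,
                                       paste0(nm, ".tsv")))
    write_table10(bio, file.path(config$out_dir, "biomarkers.tsv"))
    jsonlite::write_json(sets, file.path(config$out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
    list(norm = norm, de_t2c = de_t2c, de_t3b = de_t3b, de_all = de_all,
         de_stage = de_stage, sets = sets, biomarkers = bio)
  })

  sel <- stage("select", {
    rt <- radiomic[radiomic$subject_id %in% tumor, ]
    xm <- rt[, feature_inventory(), drop = FALSE]
    rownames(xm) <- rt$subject_id
    tr <- select_features(xm, rt$group,
                          selection_params(config$drop_ratio,
                                           config$max_features))
    jsonlite::write_json(unclass(tr)[c("selected", "score", "relevance",
                                       "redundancy", "criterion",
                                       "reason")],
                         file.path(config$out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
    tr
  })

  integ <- stage("integrate", {
    rt <- radiomic[radiomic$subject_id %in% tumor, ]
    rad <- rt[, sel$selected, drop = FALSE]
    rownames(rad) <- rt$subject_id
    pf <- perf[match(rownames(rad), perf$subject_id), ]
    rad <- cbind(rad, stats::setNames(
      pf[, c("RBV", "RBF", "beta_inv", "RT")],
      paste0("perf_", c("RBV", "RBF", "beta_inv", "RT"))))
    rad <- rad[pf$converged %in% TRUE, , drop = FALSE]  # drop failed fits
    panel <- intersect(biomarker_panel()$feature_id, rownames(tx$norm))
    expr <- t(2^tx$norm[panel, tumor, drop = FALSE] - 1)
    t3b <- clinical$subject_id[clinical$group == "T3b"]
    cmap <- correlate_features(rad, expr, samples = t3b)
    write_table10(cmap, file.path(config$out_dir, "correlations.tsv"))
    cca <- cca_ordination(expr[tumor, , drop = FALSE],
                          data.frame(stage = stage_lab))
    write_table10(data.frame(sample = rownames(cca$site_scores),
                             cca$site_scores),
                  file.path(config$out_dir, "cca_sites.tsv"))
    list(correlations = cmap, cca = cca)
  })

  evalr <- stage("classify", {
    feats <- assemble_feature_table(clinical, radiomic, perf, tx$norm,
                                    sel$selected)
    feats <- feats[tumor, , drop = FALSE]
    sets <- feature_set_specs(feats)
    ev <- evaluate_models(feats, stage_lab, sets, runs = config$runs,
                          train_frac = config$train_frac,
                          seed = scfg$seed + 601L)
    write_table10(ev$runs, file.path(config$out_dir, "auc_runs.csv"),
                  sep = ",")
    write_table10(ev$summary, file.path(config$out_dir,
                                        "auc_summary.csv"), sep = ",")
    ev
  })

  grn <- stage("grn", {
    groups <- clinical$group[match(colnames(tx$norm),
                                   clinical$subject_id)]
    mi_ids <- rownames(study$expression$mirna)
    mr_ids <- rownames(study$expression$mrna)
    mi_up <- trend_filter(tx$norm[mi_ids, , drop = FALSE], groups,
                          "increasing", config$trend_delta)
    mr_dn <- trend_filter(tx$norm[mr_ids, , drop = FALSE], groups,
                          "decreasing", config$trend_delta)
    g <- build_grn(mi_up, mr_dn, study$interactions,
                   config$hub_min_degree)
    write_table10(g$edges, file.path(config$out_dir, "grn_edges.tsv"))
    jsonlite::write_json(list(hubs = g$hubs,
                              degrees = as.list(g$degrees),
                              covered_genes = g$covered_genes),
                         file.path(config$out_dir, "grn_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    g
  })

  resolved <- unclass(config); resolved$study <- unclass(scfg)
  yaml::write_yaml(resolved, file.path(config$out_dir,
                                       "config_resolved.yaml"))
  writeLines(c(sprintf("radiostage %s",
                       as.character(utils::packageVersion("radiostage"))),
               sprintf("seed %d", scfg$seed),
               sprintf("R %s.%s", R.version$major, R.version$minor)),
             file.path(config$out_dir, "run_log.txt"))
  invisible(list(config = config, study = study, radiomic = radiomic,
                 perfusion = perf, transcriptomics = tx, selection = sel,
                 integration = integ, evaluation = evalr, grn = grn))
}

# merged per-subject feature table with the column naming contract:
# clinical columns prefixed clin_, perfusion perf_, expression by feature
# id, radiomic by canonical feature name
assemble_feature_table <- function(clinical, radiomic, perf, norm,
                                   selected) {
  ids <- clinical$subject_id
  out <- data.frame(row.names = ids)
  for (v in c("age", "tPSA", "fPSA_ratio", "trus_volume", "psa_density"))
    out[[paste0("clin_", v)]] <- clinical[[v]][match(ids,
                                                     clinical$subject_id)]
  pf <- perf[match(ids, perf$subject_id), ]
  for (v in c("RBV", "RBF", "beta_inv", "RT"))
    out[[paste0("perf_", v)]] <- pf[[v]]
  panel <- intersect(biomarker_panel()$feature_id, rownames(norm))
  for (g in panel) out[[g]] <- norm[g, ids]
  rad <- radiomic[match(ids, radiomic$subject_id), selected, drop = FALSE]
  out <- cbind(out, stats::setNames(rad, selected))
  out[stats::complete.cases(out), , drop = FALSE]
}

feature_set_specs <- function(features) {
  cn <- colnames(features)
  clin <- grep("^clin_", cn, value = TRUE)
  perf <- grep("^perf_", cn, value = TRUE)
  bio <- intersect(biomarker_panel()$feature_id, cn)
  rad <- setdiff(cn, c(clin, perf, bio))
  list(clinical = clin, transcriptomic = bio,
       radiomic = c(rad, perf),
       combined = c(clin, bio, rad, perf))
}
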