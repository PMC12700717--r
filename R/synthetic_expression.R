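# Negative-binomial count generator with planted structure:
#   * the six named staging biomarkers, shifted between T2c and T3b by
#     2^de_log2fc in their published directions (FZD4, RPS7, RPL29 and
#     miR-9-3p up in T3b; miR-374c-5p and miR-6510-3p down);
#   * stage-specific DE features (shifted vs healthy in one stage only);
#   * monotone-trend features (mRNA means decreasing healthy -> T2c -> T3b,
#     miRNA means increasing) that feed the regulatory-network stage;
#   * the remainder null.
# Per-subject sequencing-depth factors are drawn lognormal so CPM
# normalization has real work to do.

#' Generate synthetic mRNA and miRNA count matrices
#'
#' @param cfg A [study_config()].
#' @return A list with `mrna` and `mirna` count matrices (features x
#'   samples, integer), and `truth`, a data frame recording every planted
#'   effect (`feature_id`, `modality`, `role`, `direction`, `log2fc`, and
#'   the three generating group means).
#' @export
gen_expression <- function(cfg) {
  validate_config(cfg)
  subj <- subject_table(cfg)
  pan <- biomarker_panel()

  plan_modality <- function(modality, n_feat, n_specific, n_monotone) {
    bio <- pan[pan$modality == modality, ]
    need <- nrow(bio) + n_monotone + 2L * n_specific
    if (need > n_feat)
      stopf("planted %s features (%d) exceed total features (%d)",
            modality, need, n_feat)
    prefix <- if (modality == "mrna") "GENE%04d" else "miR-syn-%04d"
    ids <- c(bio$feature_id, sprintf(prefix, seq_len(n_feat - nrow(bio))))
    mono_dir <- if (modality == "mrna") "down" else "up"
    role <- c(rep("biomarker", nrow(bio)),
              rep(paste0("monotone_", mono_dir), n_monotone),
              rep("t2c_specific", n_specific),
              rep("t3b_specific", n_specific),
              rep("null", n_feat - need))
    direction <- rep(NA_character_, n_feat)
    direction[seq_len(nrow(bio))] <- bio$direction
    data.frame(feature_id = ids, modality = modality, role = role,
               direction = direction, stringsAsFactors = FALSE)
  }

  build <- function(plan, seed_off) {
    de <- cfg$de_log2fc
    with_seed(cfg$seed + seed_off, {
      n <- nrow(plan)
      base <- stats::rlnorm(n, log(100), 1)
      # planted signs for stage-specific features
      sgn <- sample(c(-1, 1), n, replace = TRUE)
      mH <- mT2 <- mT3 <- base
      for (i in seq_len(n)) {
        switch(plan$role[i],
          biomarker = {
            s <- if (plan$direction[i] == "up") 1 else -1
            mT3[i] <- base[i] * 2^(s * de)
          },
          t2c_specific = {
            mT2[i] <- base[i] * 2^(sgn[i] * de)
            plan$direction[i] <- if (sgn[i] > 0) "up" else "down"
          },
          t3b_specific = {
            mT3[i] <- base[i] * 2^(sgn[i] * de)
            plan$direction[i] <- if (sgn[i] > 0) "up" else "down"
          },
          monotone_down = {
            mH[i] <- base[i] * 2^de; mT2[i] <- base[i] * 2^(de / 2)
            plan$direction[i] <- "down"
          },
          monotone_up = {
            mT2[i] <- base[i] * 2^(de / 2); mT3[i] <- base[i] * 2^de
            plan$direction[i] <- "up"
          },
          NULL)
      }
      depth <- stats::rlnorm(nrow(subj), 0, 0.2)
      mu <- cbind(mH, mT2, mT3)[, match(subj$group,
                                        c("healthy", "T2c", "T3b"))]
      mu <- sweep(mu, 2, depth, `*`)
      counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                      size = 1 / cfg$nb_dispersion),
                       nrow = n,
                       dimnames = list(plan$feature_id, subj$subject_id))
      plan$log2fc <- ifelse(plan$role == "null", 0,
                            ifelse(grepl("monotone", plan$role), de / 2, de))
      plan$mean_healthy <- mH
      plan$mean_T2c <- mT2
      plan$mean_T3b <- mT3
      list(counts = counts, truth = plan)
    })
  }

  mr <- build(plan_modality("mrna", cfg$n_mrna, cfg$n_planted_de,
                            cfg$n_monotone_mrna), 401L)
  mi <- build(plan_modality("mirna", cfg$n_mirna, cfg$n_mirna_planted_de,
                            cfg$n_monotone_mirna), 402L)
  list(mrna = mr$counts, mirna = mi$counts,
       truth = rbind(mr$truth, mi$truth))
}

#' Generate a planted miRNA-target interaction edge list
#'
#' A bipartite miRNA -> gene graph containing exactly four hub miRNAs (drawn
#' from the monotone-increasing miRNA set) that jointly cover nine target
#' genes (drawn from the monotone-decreasing mRNA set), plus low-degree
#' decoy edges from other miRNAs.
#'
#' @param cfg A [study_config()].
#' @param truth The truth table from [gen_expression()]; regenerated from
#'   `cfg` when omitted.
#' @return A data frame with columns `mirna`, `gene`.
#' @export
gen_interactions <- function(cfg, truth = NULL) {
  validate_config(cfg)
  if (is.null(truth)) truth <- gen_expression(cfg)$truth
  hubs <- truth$feature_id[truth$role == "monotone_up"][1:4]
  targets <- truth$feature_id[truth$role == "monotone_down"][1:9]
  # degrees 3/3/2/2 over nine distinct genes; the last hub reuses one gene
  # so every hub has degree >= 2
  edges <- data.frame(
    mirna = c(rep(hubs[1], 3), rep(hubs[2], 3), rep(hubs[3], 2),
              hubs[4], hubs[4]),
    gene = c(targets[1:3], targets[4:6], targets[7:8], targets[9],
             targets[1]),
    stringsAsFactors = FALSE)
  if (cfg$n_decoy_edges > 0) {
    pool_mi <- setdiff(truth$feature_id[truth$modality == "mirna"], hubs)
    pool_g <- truth$feature_id[truth$modality == "mrna"]
    dec <- with_seed(cfg$seed + 501L, {
      data.frame(mirna = sample(pool_mi, cfg$n_decoy_edges),
                 gene = sample(pool_g, cfg$n_decoy_edges, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    edges <- rbind(edges, dec)
  }
  rownames(edges) <- NULL
  edges
}
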