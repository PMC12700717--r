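test_that("config invariants are enforced", {
  expect_error(study_config(n_healthy = 0), "cohort sizes")
  expect_error(study_config(image_size = 30), "image_size")
  expect_error(study_config(image_size = 66), "image_size")
  expect_error(study_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("every generator is a pure function of (cfg, seed)", {
  cfg <- tiny_study_config(seed = 42)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$images[[3]]$image, s2$images[[3]]$image)
  expect_identical(s1$images[[3]]$mask, s2$images[[3]]$mask)
  expect_identical(s1$expression$mrna, s2$expression$mrna)
  expect_identical(s1$expression$mirna, s2$expression$mirna)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(
    vapply(s1$tics, `[[`, numeric(1), "A_true"),
    vapply(s2$tics, `[[`, numeric(1), "A_true"))
  # a different seed changes the draws
  s3 <- simulate_study(tiny_study_config(seed = 43))
  expect_false(identical(s1$images[[3]]$image, s3$images[[3]]$image))
})

test_that("generated images have valid ROIs and group structure", {
  cfg <- tiny_study_config(seed = 7)
  imgs <- gen_images(cfg)
  expect_length(imgs, 2 * (cfg$n_healthy + cfg$n_T2c + cfg$n_T3b))
  for (rec in imgs[1:4]) {
    expect_gte(sum(rec$mask), 100)
    expect_true(all(rec$image >= 0 & rec$image <= 1))
    expect_identical(dim(rec$image), dim(rec$mask))
  }
  expect_setequal(unique(vapply(imgs, `[[`, character(1), "modality")),
                  c("Bmode", "CEUS-peak"))
})

test_that("T3b in-ROI speckle variance exceeds T2c's at positive contrast", {
  cfg <- study_config(n_healthy = 1, n_T2c = 12, n_T3b = 12,
                      image_size = 64, texture_contrast = 2, seed = 9)
  imgs <- Filter(function(r) r$modality == "Bmode", gen_images(cfg))
  v <- vapply(imgs, function(r) var(r$image[r$mask]), numeric(1))
  g <- vapply(imgs, `[[`, character(1), "group")
  expect_gt(mean(v[g == "T3b"]), mean(v[g == "T2c"]))
})

test_that("noiseless TICs follow the refill model exactly", {
  cfg <- tiny_study_config(seed = 3, tic_noise_sd = 0)
  tics <- gen_tics(cfg)
  tc <- tics[[1]]
  expect_equal(tc$intensity,
               tc$A_true * (1 - exp(-tc$beta_true * tc$t)),
               tolerance = 1e-12)
  # model forces I(0) = 0 and plateau -> A
  expect_equal(tc$A_true * (1 - exp(-tc$beta_true * 0)), 0)
  expect_gte(length(tc$t), 30)
})

test_that("expression truth table labels every planted effect", {
  cfg <- tiny_study_config(seed = 5)
  ex <- gen_expression(cfg)
  tr <- ex$truth
  expect_identical(nrow(ex$mrna), cfg$n_mrna)
  expect_identical(nrow(ex$mirna), cfg$n_mirna)
  expect_identical(sum(tr$role == "biomarker"), 6L)
  expect_identical(sum(tr$role == "t2c_specific" & tr$modality == "mrna"),
                   cfg$n_planted_de)
  expect_identical(sum(tr$role == "monotone_down"), cfg$n_monotone_mrna)
  expect_identical(sum(tr$role == "monotone_up"), cfg$n_monotone_mirna)
  # planted directions: biomarkers move between T2c and T3b as published
  pan <- merge(biomarker_panel(), tr, by = "feature_id")
  up <- pan$direction.x == "up"
  expect_true(all(pan$mean_T3b[up] > pan$mean_T2c[up]))
  expect_true(all(pan$mean_T3b[!up] < pan$mean_T2c[!up]))
  # monotone trends hold in the generating means
  mono <- tr[tr$role == "monotone_down", ]
  expect_true(all(mono$mean_healthy > mono$mean_T2c &
                    mono$mean_T2c > mono$mean_T3b))
  # a null generator plants no shifts
  tr0 <- gen_expression(tiny_study_config(seed = 5, de_log2fc = 0))$truth
  expect_equal(tr0$mean_healthy, tr0$mean_T2c)
  expect_equal(tr0$mean_T2c, tr0$mean_T3b)
  # over-planting fails loudly
  expect_error(gen_expression(tiny_study_config(n_planted_de = 200)),
               "exceed")
})

test_that("clinical draws reproduce the cohort moments", {
  cfg <- study_config(n_healthy = 2, n_T2c = 10000, n_T3b = 2, seed = 12)
  cl <- gen_clinical(cfg)
  age <- cl$age[cl$group == "T2c"]
  se <- 7.90 / sqrt(length(age))
  expect_lt(abs(mean(age) - 70.11), 3 * se)
  tv <- gen_clinical(study_config(n_healthy = 2, n_T2c = 2, n_T3b = 10000,
                                  seed = 13))
  tvol <- tv$trus_volume[tv$group == "T3b"]
  expect_lt(abs(mean(tvol) - 49.50), 3 * 19.86 / sqrt(length(tvol)) + 0.5)
  expect_true(all(cl$age > 0 & cl$tPSA > 0 & cl$trus_volume > 0))
  # published group sizes get the exact Gleason category multiset
  cl48 <- gen_clinical(study_config(seed = 1))
  expect_identical(as.vector(table(cl48$gleason[cl48$group == "T2c"])),
                   c(0L, 2L, 7L, 14L, 12L))
  expect_identical(as.vector(table(cl48$gleason[cl48$group == "T3b"])),
                   c(0L, 1L, 3L, 5L, 4L))
})

test_that("interaction graph plants 4 hubs covering 9 genes", {
  cfg <- tiny_study_config(seed = 8)
  ex <- gen_expression(cfg)
  edges <- gen_interactions(cfg, ex$truth)
  planted <- ex$truth$feature_id[ex$truth$role == "monotone_up"][1:4]
  deg <- table(edges$mirna)
  top4 <- names(sort(deg, decreasing = TRUE))[1:4]
  expect_setequal(top4, planted)
  hub_genes <- unique(edges$gene[edges$mirna %in% planted])
  expect_length(hub_genes, 9)
  # zero decoys -> only the planted edges remain
  e0 <- gen_interactions(tiny_study_config(seed = 8, n_decoy_edges = 0),
                         ex$truth)
  expect_setequal(unique(e0$mirna), planted)
})

test_that("a written study round-trips through its readers", {
  dir <- withr::local_tempdir()
  cfg <- tiny_study_config(seed = 21)
  st <- simulate_study(cfg)
  write_study(st, dir)
  counts <- read_counts(file.path(dir, "mrna_counts.tsv"))
  expect_identical(dim(counts), dim(st$expression$mrna))
  expect_equal(unname(counts), unname(st$expression$mrna))
  tics <- read_tics(file.path(dir, "tics.csv"))
  expect_length(tics, length(st$tics))
  expect_equal(tics[[2]]$intensity, st$tics[[2]]$intensity,
               tolerance = 1e-8)
  pair <- read_image_pair(
    file.path(dir, "images", sprintf("%s_Bmode.png", st$clinical$subject_id[1])),
    file.path(dir, "masks", sprintf("%s_Bmode.png", st$clinical$subject_id[1])))
  expect_identical(pair$mask, st$images[[1]]$mask)
  # 8-bit quantization on write: pixel values round-trip to 1/255
  expect_lt(max(abs(pair$image - st$images[[1]]$image)), 1 / 255)
})
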