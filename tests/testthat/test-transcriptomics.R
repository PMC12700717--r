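test_that("CPM normalization removes depth and keeps monotonicity", {
  counts <- matrix(c(1, 1, 2), 3, 1, dimnames = list(letters[1:3], "s1"))
  cpm <- 2^normalize_cpm(counts) - 1
  expect_equal(as.vector(cpm), c(250000, 250000, 500000))
  # proportional columns normalize identically
  m <- matrix(c(5, 10, 15, 10, 20, 30), 3, 2,
              dimnames = list(letters[1:3], c("a", "b")))
  n <- normalize_cpm(m)
  expect_equal(n[, 1], n[, 2])
  expect_equal(normalize_cpm(matrix(c(0, 10), 2, 1))[1, 1], 0)
  expect_error(normalize_cpm(cbind(m, zero = c(0, 0, 0))), "zero-library")
  expect_error(normalize_cpm(-m), "nonnegative")
})

test_that("the vectorized Welch test matches t.test row by row", {
  set.seed(6)
  m <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  a <- paste0("s", 1:5); b <- paste0("s", 6:12)
  de <- de_test(m, a, b)
  for (i in c(1, 17, 50)) {
    ref <- t.test(m[i, b], m[i, a])
    expect_equal(de$p[i], ref$p.value, tolerance = 1e-12)
  }
  expect_equal(de$q, p.adjust(de$p, "BH"))
})

test_that("identical groups give p = 1 everywhere and no flags", {
  m <- matrix(rep(c(1, 2, 3, 4, 5), each = 8), 5, 8, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  de <- de_test(m, paste0("s", 1:4), paste0("s", 5:8))
  expect_true(all(de$p == 1))
  expect_false(any(de$de_flag))
})

test_that("BH adjustment matches the hand-computed case", {
  # p = {0.01, 0.02, 0.04}, m = 3 -> q = {0.03, 0.03, 0.04}
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  set.seed(8)
  m <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  de <- de_test(m, paste0("s", 1:4), paste0("s", 5:8))
  # monotone in p-rank and bounded by 1
  expect_true(all(diff(de$q[order(de$p)]) >= 0))
  expect_true(all(de$q <= 1 & de$q >= de$p))
})

test_that("stage-specific set logic is exact set algebra", {
  mk <- function(flags, universe = letters[1:5]) {
    structure(data.frame(feature_id = universe,
                         log2fc = 0, p = 1, q = 1,
                         de_flag = universe %in% flags,
                         mean_a = 1, mean_b = 1,
                         stringsAsFactors = FALSE),
              class = c("de_result", "data.frame"))
  }
  s <- stage_specific_sets(mk(c("a", "b")), mk(c("b", "c")),
                           mk(c("a", "b", "c")))
  expect_identical(s$specific_T2c, "a")
  expect_identical(s$specific_T3b, "c")
  expect_identical(s$shared, "b")
  expect_identical(unname(s$venn[["T2c_and_T3b"]]), 1L)
  # disjoint flag sets: specifics equal the originals
  s2 <- stage_specific_sets(mk(c("a", "b")), mk(c("d", "e")))
  expect_setequal(s2$specific_T2c, c("a", "b"))
  expect_setequal(s2$specific_T3b, c("d", "e"))
  expect_identical(s2$shared, character(0))
  expect_error(stage_specific_sets(mk("a"), mk("a", universe = letters[2:6])),
               "universe")
})

test_that("planted stage-specific features are recovered from the generator", {
  cfg <- tiny_study_config(seed = 19)
  st <- simulate_study(cfg)
  norm <- rbind(normalize_cpm(st$expression$mrna),
                normalize_cpm(st$expression$mirna))
  ids <- split(st$clinical$subject_id, st$clinical$group)
  de2 <- de_test(norm, ids$healthy, ids$T2c)
  de3 <- de_test(norm, ids$healthy, ids$T3b)
  s <- stage_specific_sets(de2, de3)
  truth <- st$expression$truth
  planted2 <- truth$feature_id[truth$role == "t2c_specific"]
  # most planted T2c-specific features land in the T2c-specific set
  expect_gt(mean(planted2 %in% s$specific_T2c), 0.6)
})

test_that("the biomarker filter passes planted panels with quoted directions", {
  cfg <- tiny_study_config(seed = 23)
  st <- simulate_study(cfg)
  norm <- rbind(normalize_cpm(st$expression$mrna),
                normalize_cpm(st$expression$mirna))
  ids <- split(st$clinical$subject_id, st$clinical$group)
  de <- de_test(norm, ids$T2c, ids$T3b)
  bio <- biomarker_filter(de)
  pan <- biomarker_panel()
  hit <- merge(bio, pan, by = "feature_id")
  expect_gte(nrow(hit), 5)
  expect_true(all(hit$direction.x == hit$direction.y))
  # null generator: planted panel has no systematic effect
  st0 <- simulate_study(tiny_study_config(seed = 23, de_log2fc = 0))
  norm0 <- rbind(normalize_cpm(st0$expression$mrna),
                 normalize_cpm(st0$expression$mirna))
  de0 <- de_test(norm0, ids$T2c, ids$T3b)
  expect_lte(nrow(biomarker_filter(de0)), 1)
  expect_error(biomarker_filter(de0, panel = "NOT_A_GENE"), "missing")
})

test_that("hypergeometric enrichment matches closed forms", {
  universe <- paste0("g", 1:10)
  coll <- list(setA = paste0("g", 1:5), setB = paste0("g", 6:10))
  res <- enrich_sets(paste0("g", 1:4), coll, universe)
  # overlap 4 of K=5 in n=4 draws from N=10: p = C(5,4)/C(10,4) = 5/210
  expect_equal(res$p[res$set == "setA"], 5 / 210, tolerance = 1e-12)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  # empty query: all p = 1
  res0 <- enrich_sets(character(0), coll, universe)
  expect_true(all(res0$p == 1))
  expect_error(enrich_sets("g1", coll, character(0)), "empty universe")
})
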