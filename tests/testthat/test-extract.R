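test_that("the inventory has 368 features in 6 + 40 + 322 layout", {
  inv <- feature_inventory()
  expect_length(inv, 368)
  expect_length(unique(inv), 368)
  parsed <- lapply(inv, parse_feature_name)
  sb <- vapply(parsed, `[[`, character(1), "subband")
  fam <- vapply(parsed, `[[`, character(1), "family")
  expect_identical(sum(sb == "native" & fam == "Global"), 6L)
  expect_identical(sum(sb == "native" & fam != "Global"), 40L)
  expect_identical(sum(sb != "native"), 322L)
  # per-family sizes of the higher-order group: 9 + 13 + 13 + 5
  expect_identical(as.vector(table(fam[sb == "native"])[c("GLCM", "GLRLM",
                                                          "GLSZM", "NGTDM")]),
                   c(9L, 13L, 13L, 5L))
})

test_that("feature names render and parse canonically", {
  expect_identical(render_feature_name("native", "NGTDM", "Busyness"),
                   "NGTDM-Busyness")
  expect_identical(render_feature_name("cv2", "GLSZM", "LZHGE"),
                   "cv2-GLSZM-LZHGE")
  p <- parse_feature_name("ca2-GLRLM-RLV")
  expect_identical(p, list(subband = "ca2", family = "GLRLM",
                           feature = "RLV"))
  expect_identical(parse_feature_name("Global-Mean")$subband, "native")
  expect_error(parse_feature_name("cv9-GLSZM-LZHGE"), "unparseable")
  expect_error(parse_feature_name("GLSZM-Bogus"), "unknown")
  # round trip over the whole inventory
  for (nm in feature_inventory()) {
    p <- parse_feature_name(nm)
    expect_identical(render_feature_name(p$subband, p$family, p$feature),
                     nm)
  }
})

test_that("reported feature names from the staging study are all present", {
  inv <- feature_inventory()
  used <- c("ca2-GLRLM-RLV", "cv2-GLSZM-LZHGE", "ca2-GLSZM-LZE",
            "cv2-GLSZM-LZE", "ch2-GLSZM-LZE", "cv2-GLSZM-LZLGE",
            "cv1-GLRLM-GLV", "ch2-GLSZM-LGZE", "ch2-GLRLM-LGRE",
            "ch1-Global-Variance", "ch1-Global-Skewness",
            "ca2-NGTDM-Strength", "NGTDM-Busyness", "cd1-NGTDM-Coarseness",
            "ch2-Global-Skewness", "ca2-GLCM-Correlation",
            "cv1-GLSZM-ZSV", "ch1-GLRLM-RLV", "ca2-GLSZM-LGZE")
  expect_true(all(used %in% inv))
})

test_that("extract_all yields 368 deterministic, named values", {
  set.seed(13)
  img <- matrix(runif(64 * 64), 64, 64)
  mask <- outer(1:64, 1:64, function(r, c)
    ((r - 32) / 20)^2 + ((c - 32) / 14)^2 <= 1)
  fv <- extract_all(img, mask, ng = 8)
  expect_length(fv, 368)
  expect_identical(names(fv), feature_inventory())
  expect_false(anyNA(fv))
  expect_identical(fv, extract_all(img, mask, ng = 8))
})

test_that("every group-2 feature agrees with the full formula oracle", {
  set.seed(99)
  img <- matrix(runif(64), 8, 8)
  q <- quantize_roi(img, matrix(TRUE, 8, 8), 4)
  G <- oracle_glcm(q$levels, 4, default_offsets())
  expect_equal(unname(glcm_features(q)), unname(oracle_glcm_features(G)),
               tolerance = 1e-12)
  M <- oracle_glrlm(q$levels, 4, c("0", "45", "90", "135"))
  expect_equal(unname(glrlm_features(q))[c(3, 4, 5, 1, 2, 6:13)],
               oracle_rl_sz(M, 64 * 4), tolerance = 1e-12)
  Z <- oracle_glszm(q$levels, 4)
  expect_equal(unname(glszm_features(q))[c(3, 4, 5, 1, 2, 6:13)],
               oracle_rl_sz(Z, 64), tolerance = 1e-12)
})

test_that("an empty decimated sub-band mask produces sentinel values", {
  mask <- matrix(FALSE, 32, 32)
  mask[11, 11 + 0:9] <- TRUE  # a thin 1x10 line: survives no decimation
  img <- matrix(runif(32 * 32), 32, 32)
  w <- capture_warnings(fv <- extract_all(img, mask, ng = 4))
  expect_true(all(grepl("sentinel", w)))
  expect_gte(length(w), 1)
  expect_length(fv, 368)
  expect_false(anyNA(fv))
})

test_that("peak frame selection maximizes mean in-mask intensity", {
  mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  frames <- list(matrix(1, 2, 2), matrix(c(9, 0, 0, 0), 2, 2),
                 matrix(2, 2, 2))
  expect_identical(peak_frame(frames, mask), frames[[2]])
  expect_identical(peak_frame(frames[2], mask), frames[[2]])
})

test_that("extract_table produces one row per subject and modality filter works", {
  cfg <- tiny_study_config(seed = 17)
  imgs <- gen_images(cfg)[1:6]
  tab <- extract_table(imgs, modality = "Bmode", ng = 8)
  expect_identical(nrow(tab), 3L)
  expect_identical(ncol(tab), 3L + 368L)
  expect_true(all(feature_inventory() %in% colnames(tab)))
})
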