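test_that("quantization uses equal-width bins over the in-mask range", {
  img <- matrix(0:255, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  q <- quantize_roi(img, mask, ng = 2)
  expect_identical(q$levels[img < 128], rep(1L, sum(img < 128)))
  expect_identical(q$levels[img >= 128], rep(2L, sum(img >= 128)))
  q4 <- quantize_roi(matrix(c(10, 20, 30, 40), 2, 2),
                     matrix(TRUE, 2, 2), ng = 4)
  expect_setequal(as.vector(q4$levels), 1:4)
  qc <- quantize_roi(matrix(5, 3, 3), matrix(TRUE, 3, 3), ng = 8)
  expect_true(all(qc$levels == 1L))
  expect_error(quantize_roi(img, matrix(FALSE, 16, 16), 4), "empty mask")
  # out-of-mask pixels carry no level
  m <- matrix(TRUE, 16, 16); m[1, ] <- FALSE
  expect_true(all(is.na(quantize_roi(img, m, 4)$levels[1, ])))
})

test_that("global features match closed forms and hand computations", {
  v <- matrix(c(1, 2, 3, 4), 1)
  g <- global_features(v, matrix(TRUE, 1, 4))
  expect_equal(g[["Mean"]], 2.5)
  expect_equal(g[["Variance"]], 1.25)
  g2 <- global_features(matrix(c(1, 1, 1, 5), 1), matrix(TRUE, 1, 4))
  expect_equal(g2[["Skewness"]], (24 / 4) / 3^1.5, tolerance = 1e-12)
  gc <- global_features(matrix(7, 2, 2), matrix(TRUE, 2, 2))
  expect_equal(unname(gc[c("Variance", "Skewness", "Entropy", "Energy")]),
               c(0, 0, 0, 1))
})

test_that("glcm features match hand-enumerated pair counts", {
  # [[1,2],[1,2]] with single horizontal offset: pairs (1,2) and (2,1) x2
  q <- structure(list(levels = matrix(c(1L, 1L, 2L, 2L), 2, 2),
                      ng = 2L, mask = matrix(TRUE, 2, 2)),
                 class = "quantized_roi")
  G <- glcm_matrix(q, list(c(0L, 1L)))
  expect_equal(G, matrix(c(0, 2, 2, 0), 2, 2))
  f <- glcm_features(q, list(c(0L, 1L)))
  expect_equal(f[["Contrast"]], 1)
  expect_equal(f[["Correlation"]], -1)
  # checkerboard with axis-aligned offsets: all pairs are discordant
  ck <- structure(list(levels = outer(1:4, 1:4, function(i, j)
    1L + (i + j) %% 2L), ng = 2L, mask = matrix(TRUE, 4, 4)),
    class = "quantized_roi")
  fck <- glcm_features(ck, list(c(0L, 1L), c(1L, 0L)))
  expect_equal(fck[["Correlation"]], -1)
  # constant ROI sentinels
  qc <- quantize_roi(matrix(3, 4, 4), matrix(TRUE, 4, 4), 8)
  fc <- glcm_features(qc)
  expect_equal(unname(fc[c("Contrast", "MaxProbability", "Correlation")]),
               c(0, 1, 0))
})

test_that("glrlm features match hand-enumerated runs", {
  q <- structure(list(levels = matrix(c(1L, 1L, 2L), 1, 3), ng = 2L,
                      mask = matrix(TRUE, 1, 3)),
                 class = "quantized_roi")
  f <- glrlm_features(q, directions = "0")
  expect_equal(f[["RP"]], 2 / 3)
  # constant N-pixel row: one run of length N
  n <- 7
  qr <- structure(list(levels = matrix(1L, 1, n), ng = 2L,
                       mask = matrix(TRUE, 1, n)),
                  class = "quantized_roi")
  fr <- glrlm_features(qr, directions = "0")
  expect_equal(fr[["LRE"]], n^2)
  expect_equal(fr[["SRE"]], 1 / n^2)
  # all runs length 1 -> zero run-length variance
  qa <- structure(list(levels = matrix(c(1L, 2L, 1L, 2L), 1, 4), ng = 2L,
                       mask = matrix(TRUE, 1, 4)),
                  class = "quantized_roi")
  expect_equal(glrlm_features(qa, "0")[["RLV"]], 0)
})

test_that("glszm features match hand-enumerated zones", {
  # constant 10-pixel ROI: one zone of size 10
  mask <- matrix(FALSE, 3, 4); mask[1:10] <- TRUE
  lev <- matrix(NA_integer_, 3, 4); lev[mask] <- 1L
  q <- structure(list(levels = lev, ng = 2L, mask = mask),
                 class = "quantized_roi")
  f <- glszm_features(q)
  expect_equal(f[["ZP"]], 1 / 10)
  expect_equal(f[["LZE"]], 100)
  # [[1,1],[2,3]]: zones (1,2),(2,1),(3,1)
  q2 <- structure(list(levels = matrix(c(1L, 2L, 1L, 3L), 2, 2), ng = 3L,
                       mask = matrix(TRUE, 2, 2)),
                  class = "quantized_roi")
  f2 <- glszm_features(q2)
  expect_equal(f2[["ZP"]], 3 / 4)
  expect_equal(f2[["LZHGE"]], 17 / 3)
  # two zones of equal size -> zero zone-size variance
  q3 <- structure(list(levels = matrix(c(1L, 2L), 1, 2), ng = 2L,
                       mask = matrix(TRUE, 1, 2)),
                  class = "quantized_roi")
  expect_equal(glszm_features(q3)[["ZSV"]], 0)
})

test_that("glszm zones are 8-connected", {
  # two diagonal pixels of the same level form ONE zone
  lev <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  q <- structure(list(levels = lev, ng = 2L, mask = matrix(TRUE, 2, 2)),
                 class = "quantized_roi")
  M <- glszm_matrix(q)
  expect_equal(M[1, 2], 1)  # level 1: one zone of size 2
  expect_equal(M[2, 2], 1)  # level 2: one zone of size 2
})

test_that("ngtdm features match the hand-enumerated neighbor means", {
  lev <- matrix(1L, 3, 3); lev[2, 2] <- 2L
  q <- structure(list(levels = lev, ng = 2L, mask = matrix(TRUE, 3, 3)),
                 class = "quantized_roi")
  tb <- ngtdm_table(q)
  expect_equal(tb$n, c(8, 1))
  # center: |2 - 1| = 1; corners: |1 - 4/3| each; edges: |1 - 6/5| each
  expect_equal(tb$s, c(4 * (1 / 3) + 4 * (1 / 5), 1), tolerance = 1e-12)
  f <- ngtdm_features(q)
  o <- oracle_ngtdm_features(oracle_ngtdm(lev, 2), 2)
  expect_equal(f, o, tolerance = 1e-12)
  # constant ROI: coarseness capped, others zero
  qc <- quantize_roi(matrix(1, 4, 4), matrix(TRUE, 4, 4), 4)
  fc <- ngtdm_features(qc)
  expect_equal(unname(fc[c("Busyness", "Strength")]), c(0, 0))
  expect_equal(fc[["Coarseness"]], 1e6)
})

test_that("all matrix families agree with enumeration oracles on random images", {
  offs <- default_offsets()
  dirs <- c("0", "45", "90", "135")
  for (s in 1:12) {
    q <- random_quantized(sample(4:12, 1), sample(4:12, 1),
                          ng = sample(2:5, 1),
                          mask_frac = sample(c(1, 0.8), 1), seed = s)
    expect_equal(glcm_matrix(q, offs), oracle_glcm(q$levels, q$ng, offs))
    expect_equal(glrlm_matrix(q, dirs), oracle_glrlm(q$levels, q$ng, dirs))
    expect_equal(glszm_matrix(q), oracle_glszm(q$levels, q$ng))
    nt <- ngtdm_table(q); no <- oracle_ngtdm(q$levels, q$ng)
    expect_equal(nt$n, no$n)
    expect_equal(nt$s, no$s, tolerance = 1e-12)
  }
})

test_that("group-2 features are invariant to intensity shift and scale", {
  set.seed(31)
  img <- matrix(runif(144), 12, 12)
  mask <- matrix(TRUE, 12, 12)
  f1 <- function(im) {
    q <- quantize_roi(im, mask, 8)
    c(glcm_features(q), glrlm_features(q), glszm_features(q),
      ngtdm_features(q))
  }
  expect_equal(f1(img), f1(3.7 * img + 11), tolerance = 1e-10)
})

test_that("normalized texture matrices sum to one and glcm is symmetric", {
  q <- random_quantized(10, 10, 4, seed = 77)
  G <- glcm_matrix(q)
  expect_equal(G, t(G))
  expect_equal(sum(G / sum(G)), 1)
  M <- glrlm_matrix(q)
  expect_equal(sum(M / sum(M)), 1)
  Z <- glszm_matrix(q)
  # total zone-size mass equals the number of connected zones
  expect_equal(sum(Z), nrow(oracle_zones(q$levels)))
})
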