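# Scalar texture features from the count structures. Formulas are the
# standard Haralick (GLCM), Galloway/Chu (GLRLM), Thibault (GLSZM) and
# Amadasun-King (NGTDM) definitions on the normalized matrices. Degenerate
# inputs produce defined sentinels rather than NaN: correlation-type
# features on zero-variance input are 0, and the NGTDM coarseness is capped
# at 1e6 when its denominator vanishes.

COARSENESS_CAP <- 1e6

#' Global first-order features
#'
#' Population moments of in-mask intensities (Mean, Variance, Skewness,
#' Kurtosis) plus Entropy and Energy of their `ng`-bin equal-width
#' histogram. Skewness and Kurtosis of a constant region are 0.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix.
#' @param ng Histogram bin count for Entropy/Energy.
#' @return Named numeric vector of 6 features.
#' @export
global_features <- function(image, mask, ng = 32) {
  if (!any(mask)) stopf("empty mask")
  v <- image[mask]
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  skew <- if (s2 == 0) 0 else mean((v - mu)^3) / s2^1.5
  kurt <- if (s2 == 0) 0 else mean((v - mu)^4) / s2^2
  if (min(v) == max(v)) {
    p <- 1
  } else {
    breaks <- seq(min(v), max(v), length.out = ng + 1)
    h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), ng)
    p <- h / sum(h)
    p <- p[p > 0]
  }
  c(Mean = mu, Variance = s2, Skewness = skew, Kurtosis = kurt,
    Entropy = -sum(p * log2(p)), Energy = sum(p^2))
}

#' Gray-level co-occurrence features
#'
#' Nine Haralick-type features of the normalized, symmetrized co-occurrence
#' matrix aggregated over offsets.
#'
#' @param q A [quantize_roi()] result.
#' @param offsets Passed to [glcm_matrix()].
#' @return Named numeric vector: Energy, Contrast, Correlation, Homogeneity,
#'   Entropy, Variance, SumAverage, Dissimilarity, MaxProbability.
#' @export
glcm_features <- function(q, offsets = default_offsets()) {
  if (sum(q$mask) < 2) stopf("need at least 2 in-mask pixels")
  G <- glcm_matrix(q, offsets)
  tot <- sum(G)
  if (tot == 0) stopf("no co-occurring in-mask pixel pairs")
  P <- G / tot
  ng <- q$ng
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mu_x <- sum(i * P)          # symmetric: mu_x == mu_y
  var_x <- sum((i - mu_x)^2 * P)
  corr <- if (var_x == 0) 0 else sum((i - mu_x) * (j - mu_x) * P) / var_x
  pp <- P[P > 0]
  c(Energy = sum(P^2),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    Homogeneity = sum(P / (1 + (i - j)^2)),
    Entropy = -sum(pp * log2(pp)),
    Variance = var_x,
    SumAverage = sum((i + j) * P),
    Dissimilarity = sum(abs(i - j) * P),
    MaxProbability = max(P))
}

# shared emphasis-style formulas for run-length and size-zone matrices;
# `M` is the Ng x K count matrix, K indexing run length / zone size,
# `npix` the number of in-mask pixels
rl_sz_features <- function(M, npix, prefix) {
  nruns <- sum(M)
  P <- M / nruns
  ng <- nrow(M); kmax <- ncol(M)
  i <- matrix(seq_len(ng), ng, kmax)
  k <- matrix(seq_len(kmax), ng, kmax, byrow = TRUE)
  mu_i <- sum(i * P)
  mu_k <- sum(k * P)
  vals <- c(
    sum(P / k^2),                     # short emphasis
    sum(P * k^2),                     # long emphasis
    sum(rowSums(M)^2) / nruns,        # gray-level nonuniformity
    sum(colSums(M)^2) / nruns,        # length/size nonuniformity
    nruns / npix,                     # percentage
    sum(P / i^2),                     # low gray-level
    sum(P * i^2),                     # high gray-level
    sum(P / (i^2 * k^2)),             # short + low
    sum(P * i^2 / k^2),               # short + high
    sum(P * k^2 / i^2),               # long + low
    sum(P * i^2 * k^2),               # long + high
    sum(P * (i - mu_i)^2),            # gray-level variance
    sum(P * (k - mu_k)^2))            # length/size variance
  names(vals) <- switch(prefix,
    run = c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE",
            "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"),
    zone = c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE",
             "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"))
  vals
}

#' Gray-level run-length features
#'
#' Thirteen standard run-length features of the normalized run matrix
#' (counts summed over directions).
#'
#' @param q A [quantize_roi()] result.
#' @param directions Passed to [glrlm_matrix()].
#' @return Named numeric vector: SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
#'   SRHGE, LRLGE, LRHGE, GLV, RLV.
#' @export
glrlm_features <- function(q, directions = c("0", "45", "90", "135")) {
  M <- glrlm_matrix(q, directions)
  rl_sz_features(M, sum(q$mask) * length(directions), "run")
}

#' Gray-level size-zone features
#'
#' Thirteen standard size-zone features of the normalized zone matrix
#' (zones are 8-connected components of equal level).
#'
#' @param q A [quantize_roi()] result.
#' @return Named numeric vector: SZE, LZE, GLN, ZSN, ZP, LGZE, HGZE, SZLGE,
#'   SZHGE, LZLGE, LZHGE, GLV, ZSV.
#' @export
glszm_features <- function(q) {
  M <- glszm_matrix(q)
  rl_sz_features(M, sum(q$mask), "zone")
}

#' Neighborhood gray-tone difference features
#'
#' The five Amadasun-King features (Coarseness, Contrast, Busyness,
#' Complexity, Strength) from the per-level neighborhood-difference table.
#' Coarseness is capped at 1e6 when its denominator is 0; Busyness,
#' Contrast and Strength of a constant region are 0.
#'
#' @param q A [quantize_roi()] result.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(q) {
  tb <- ngtdm_table(q)
  n <- tb$n; s <- tb$s
  N <- sum(n)
  p <- n / N
  pres <- which(p > 0)
  ngp <- length(pres)
  lv <- seq_along(p)
  denom_coarse <- sum(p * s)
  coarse <- if (denom_coarse == 0) COARSENESS_CAP else 1 / denom_coarse
  if (ngp > 1) {
    pi_ <- p[pres]; li <- lv[pres]; si <- s[pres]
    dif2 <- outer(li, li, `-`)^2
    contrast <- sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1)) * sum(s) / N
    bdenom <- sum(abs(outer(li * pi_, li * pi_, `-`)))
    busy <- if (bdenom == 0) 0 else denom_coarse / bdenom
    pij <- outer(pi_, pi_, `+`)
    cplx <- sum(abs(outer(li, li, `-`)) *
                  (outer(pi_ * si, pi_ * si, function(a, b) a + b)) / pij) / N
    strdenom <- sum(s)
    strength <- if (strdenom == 0) 0 else sum(pij * dif2) / strdenom
  } else {
    contrast <- 0; busy <- 0; strength <- 0; cplx <- 0
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = cplx, Strength = strength)
}
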