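# Two-level separable discrete wavelet transform with periodic extension
# and orthonormal filters (Haar by default, Daubechies-2 optionally). Rows
# index the vertical axis: the "ch" bands are high-pass across rows and so
# respond to horizontal edges, "cv" to vertical edges, "cd" to diagonal
# structure. The level-1 approximation is decomposed again into
# ca2/ch2/cv2/cd2; level-1 details are retained as ch1/cv1/cd1.
#
# ROI masks are decimated alongside: a decimated cell is in-mask iff every
# original cell under the analysis filter's support is in-mask.

wavelet_filters <- function(wavelet = c("haar", "db2")) {
  wavelet <- match.arg(wavelet)
  lo <- switch(wavelet,
               haar = c(1, 1) / sqrt(2),
               db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) /
                 (4 * sqrt(2)))
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)  # quadrature mirror
  list(lo = lo, hi = hi)
}

# one periodized analysis step along columns of x (i.e., down the rows):
# returns rbind-compatible low and high halves, each nrow(x)/2 rows
dwt_step_rows <- function(x, filt) {
  n <- nrow(x); L <- length(filt$lo)
  half <- n / 2
  lo <- matrix(0, half, ncol(x)); hi <- lo
  for (tap in seq_len(L)) {
    idx <- (2 * seq_len(half) - 2 + tap - 1) %% n + 1
    lo <- lo + filt$lo[tap] * x[idx, , drop = FALSE]
    hi <- hi + filt$hi[tap] * x[idx, , drop = FALSE]
  }
  list(lo = lo, hi = hi)
}

dwt2_level <- function(x, filt) {
  v <- dwt_step_rows(x, filt)
  lo <- dwt_step_rows(t(v$lo), filt)   # now along columns
  hi <- dwt_step_rows(t(v$hi), filt)
  list(ca = t(lo$lo), cv = t(lo$hi), ch = t(hi$lo), cd = t(hi$hi))
}

# decimated mask: TRUE iff all original cells under the filter support
# (periodized window of length L in each axis) are in-mask
decimate_mask <- function(mask, L) {
  n <- nrow(mask); m <- ncol(mask)
  keep_rows <- matrix(TRUE, n / 2, m)
  for (tap in seq_len(L)) {
    idx <- (2 * seq_len(n / 2) - 2 + tap - 1) %% n + 1
    keep_rows <- keep_rows & mask[idx, , drop = FALSE]
  }
  out <- matrix(TRUE, n / 2, m / 2)
  for (tap in seq_len(L)) {
    idx <- (2 * seq_len(m / 2) - 2 + tap - 1) %% m + 1
    out <- out & keep_rows[, idx, drop = FALSE]
  }
  out
}

#' Two-level wavelet decomposition of a masked image
#'
#' @param image Numeric matrix; both dimensions must be divisible by 4.
#' @param mask Logical ROI matrix of the same dimensions.
#' @param wavelet `"haar"` (default) or `"db2"`; both orthonormal, periodic
#'   extension.
#' @return Named list of 7 sub-bands (`ch1`, `cv1`, `cd1`, `ca2`, `ch2`,
#'   `cv2`, `cd2`), each a list with `image` and the decimated `mask`.
#' @export
wavelet_decompose <- function(image, mask, wavelet = "haar") {
  if (any(dim(image) %% 4 != 0))
    stopf("image dimensions must be divisible by 4, got %dx%d",
          nrow(image), ncol(image))
  stopifnot(all(dim(image) == dim(mask)))
  filt <- wavelet_filters(wavelet)
  L <- length(filt$lo)
  lev1 <- dwt2_level(image, filt)
  m1 <- decimate_mask(mask, L)
  lev2 <- dwt2_level(lev1$ca, filt)
  m2 <- decimate_mask(m1, L)
  list(ch1 = list(image = lev1$ch, mask = m1),
       cv1 = list(image = lev1$cv, mask = m1),
       cd1 = list(image = lev1$cd, mask = m1),
       ca2 = list(image = lev2$ca, mask = m2),
       ch2 = list(image = lev2$ch, mask = m2),
       cv2 = list(image = lev2$cv, mask = m2),
       cd2 = list(image = lev2$cd, mask = m2))
}
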