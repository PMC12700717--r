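#' Quantize in-mask intensities to Ng gray levels
#'
#' Equal-width bins spanning the in-mask intensity range `[min, max]`. A
#' constant region maps every pixel to level 1. Pixels outside the mask are
#' `NA` and excluded from all downstream statistics.
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix of the same dimensions (the ROI).
#' @param ng Number of gray levels (>= 2).
#' @return An object of class `quantized_roi`: list with `levels` (integer
#'   matrix, `NA` outside the mask), `ng`, `mask`.
#' @export
quantize_roi <- function(image, mask, ng = 32) {
  if (!any(mask)) stopf("empty mask")
  if (ng < 2) stopf("ng must be >= 2")
  stopifnot(all(dim(image) == dim(mask)))
  v <- image[mask]
  lev <- matrix(NA_integer_, nrow(image), ncol(image))
  rng <- range(v)
  if (rng[1] == rng[2]) {
    lev[mask] <- 1L
  } else {
    breaks <- seq(rng[1], rng[2], length.out = ng + 1)
    lev[mask] <- as.integer(
      findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE))
  }
  structure(list(levels = lev, ng = as.integer(ng), mask = mask),
            class = "quantized_roi")
}
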