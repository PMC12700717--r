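# Synthetic ultrasound-like image model: a smooth background modulated by
# multiplicative gamma speckle (unit mean; the shape parameter sets the
# speckle variance). Inside the ROI the tumor stage shifts two texture
# parameters -- speckle variance (gamma shape) and correlation length
# (partial 3x3 smoothing) -- by an amount scaled by `texture_contrast`, so
# that first-order and matrix-based texture features separate T2c from T3b.
# CEUS peak-enhancement frames additionally brighten the ROI by a
# group-dependent perfusion factor.

smooth3x3 <- function(x) {
  # periodic 3x3 box filter (keeps dimensions, cheap, no edge shrinkage)
  n <- nrow(x); m <- ncol(x)
  up <- x[c(2:n, 1), ]; dn <- x[c(n, 1:(n - 1)), ]
  s <- x + up + dn
  (s + s[, c(2:m, 1)] + s[, c(m, 1:(m - 1))]) / 9
}

ellipse_mask <- function(size, cx, cy, a, b, theta = 0) {
  xy <- expand.grid(r = seq_len(size), c = seq_len(size))
  dx <- xy$c - cx; dy <- xy$r - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  matrix((u / a)^2 + (v / b)^2 <= 1, size, size)
}

# per-group speckle parameters at a given contrast
speckle_shape <- function(group, contrast) {
  base <- 6
  if (group == "T3b") base / (1 + contrast) else base
}

smooth_weight <- function(group, contrast) {
  if (group == "T3b") contrast / (2 * (1 + contrast)) else 0
}

ceus_enhancement <- function(group, contrast) {
  switch(group, healthy = 0.2, T2c = 0.5, T3b = 0.5 + 0.15 * contrast)
}

#' Generate synthetic B-mode and CEUS peak-frame images
#'
#' One image pair (B-mode and CEUS at peak enhancement) per subject, each
#' with an elliptical ROI mask of at least 100 pixels. Speckle is gamma
#' multiplicative noise over a smooth background; within the ROI the T3b
#' stage increases speckle variance and correlation length relative to T2c
#' by an amount controlled by `cfg$texture_contrast` (0 = identical texture
#' distributions across groups).
#'
#' @param cfg A [study_config()].
#' @return A list with one element per subject x modality, each a list with
#'   `subject_id`, `group`, `modality` (`"Bmode"` or `"CEUS-peak"`), `image`
#'   (numeric matrix in \[0, 1\]) and `mask` (logical matrix).
#' @export
gen_images <- function(cfg) {
  validate_config(cfg)
  subj <- subject_table(cfg)
  size <- cfg$image_size
  with_seed(cfg$seed + 201L, {
    out <- vector("list", 2L * nrow(subj))
    k <- 0L
    for (i in seq_len(nrow(subj))) {
      g <- as.character(subj$group[i])
      # ROI: jittered centered ellipse
      a <- size * 0.28 * stats::runif(1, 0.9, 1.1)
      b <- size * 0.20 * stats::runif(1, 0.9, 1.1)
      th <- stats::runif(1, 0, pi)
      cx <- size / 2 + stats::runif(1, -size * 0.05, size * 0.05)
      cy <- size / 2 + stats::runif(1, -size * 0.05, size * 0.05)
      mask <- ellipse_mask(size, cx, cy, a, b, th)
      if (sum(mask) < 100)
        stopf("image_size %d too small: ROI ellipse has %d < 100 pixels",
              size, sum(mask))
      # smooth background: low-frequency sinusoidal shading
      ph <- stats::runif(2, 0, 2 * pi)
      gr <- outer(seq_len(size), seq_len(size), function(r, c)
        0.55 + 0.15 * sin(2 * pi * r / size + ph[1]) *
          cos(2 * pi * c / size + ph[2]))
      for (mod in c("Bmode", "CEUS-peak")) {
        kin <- speckle_shape(g, cfg$texture_contrast)
        sp_out <- matrix(stats::rgamma(size * size, shape = 6, rate = 6),
                         size, size)
        sp_in <- matrix(stats::rgamma(size * size, shape = kin, rate = kin),
                        size, size)
        w <- smooth_weight(g, cfg$texture_contrast)
        if (w > 0) sp_in <- (1 - w) * sp_in + w * smooth3x3(sp_in)
        sp <- ifelse(mask, sp_in, sp_out)
        img <- gr * sp
        if (mod == "CEUS-peak")
          img[mask] <- img[mask] * (1 + ceus_enhancement(g, cfg$texture_contrast))
        img <- img / max(img)
        k <- k + 1L
        out[[k]] <- list(subject_id = subj$subject_id[i], group = g,
                         modality = mod, image = img, mask = mask)
      }
    }
    out
  })
}
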