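# The full feature inventory: 6 global first-order features, 40
# matrix-based ("higher-order") features (9 GLCM + 13 GLRLM + 13 GLSZM +
# 5 NGTDM) on the native image, and the same 46 features on each of 7
# wavelet sub-bands (322 in total), giving 368 named features per image.

subband_order <- c("ch1", "cv1", "cd1", "ca2", "ch2", "cv2", "cd2")

family_features <- list(
  Global = c("Mean", "Variance", "Skewness", "Kurtosis", "Entropy",
             "Energy"),
  GLCM = c("Energy", "Contrast", "Correlation", "Homogeneity", "Entropy",
           "Variance", "SumAverage", "Dissimilarity", "MaxProbability"),
  GLRLM = c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE", "SRLGE",
            "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV"),
  GLSZM = c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE", "SZLGE",
            "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV"),
  NGTDM = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength"))

#' Render and parse canonical feature names
#'
#' Canonical form is `"<subband>-<family>-<feature>"` with ASCII hyphens,
#' the sub-band component omitted for native (undecomposed) features, e.g.
#' `"NGTDM-Busyness"` or `"cv2-GLSZM-LZHGE"`.
#'
#' @param subband One of `"native"`, `"ca2"`, `"ch1"`, `"ch2"`, `"cv1"`,
#'   `"cv2"`, `"cd1"`, `"cd2"`.
#' @param family One of `"Global"`, `"GLCM"`, `"GLRLM"`, `"GLSZM"`,
#'   `"NGTDM"`.
#' @param feature Short feature code (e.g. `"LZHGE"`).
#' @return `render_feature_name()`: a string; `parse_feature_name()`: a list
#'   with `subband`, `family`, `feature`.
#' @export
render_feature_name <- function(subband, family, feature) {
  if (subband == "native") paste(family, feature, sep = "-")
  else paste(subband, family, feature, sep = "-")
}

#' @param name Canonical feature-name string.
#' @rdname render_feature_name
#' @export
parse_feature_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  fams <- names(family_features)
  if (length(parts) == 2 && parts[1] %in% fams) {
    out <- list(subband = "native", family = parts[1], feature = parts[2])
  } else if (length(parts) == 3 && parts[1] %in% subband_order &&
             parts[2] %in% fams) {
    out <- list(subband = parts[1], family = parts[2], feature = parts[3])
  } else stopf("unparseable feature name '%s'", name)
  if (!out$feature %in% family_features[[out$family]])
    stopf("unknown %s feature '%s'", out$family, out$feature)
  out
}

#' The canonical 368-feature inventory
#'
#' @param wavelet Unused placeholder kept for interface symmetry.
#' @return Character vector of 368 canonical feature names in extraction
#'   order: 6 native Global, 40 native higher-order, then 46 per sub-band.
#' @export
feature_inventory <- function(wavelet = "haar") {
  one_band <- function(sb) {
    unlist(lapply(names(family_features), function(fam)
      vapply(family_features[[fam]], function(f)
        render_feature_name(sb, fam, f), character(1))),
      use.names = FALSE)
  }
  c(one_band("native"), unlist(lapply(subband_order, one_band),
                               use.names = FALSE))
}

# the 46 features of one (image, mask) band; empty/degenerate masks yield
# 0-sentinels with a warning
band_features <- function(image, mask, ng, band_label) {
  n_feat <- sum(lengths(family_features))
  if (sum(mask) < 2) {
    warning(sprintf(
      "sub-band '%s': decimated mask has %d in-mask pixels; sentinel 0s",
      band_label, sum(mask)), call. = FALSE)
    return(rep(0, n_feat))
  }
  q <- quantize_roi(image, mask, ng)
  c(global_features(image, mask, ng), glcm_features(q), glrlm_features(q),
    glszm_features(q), ngtdm_features(q))
}

#' Extract the full 368-feature vector from one image
#'
#' @param image Numeric matrix (dimensions divisible by 4).
#' @param mask Logical ROI matrix.
#' @param ng Gray-level count for quantization and histograms.
#' @param wavelet Wavelet for the sub-band decomposition.
#' @return Named numeric vector of exactly 368 features in inventory order.
#' @export
extract_all <- function(image, mask, ng = 32, wavelet = "haar") {
  bands <- wavelet_decompose(image, mask, wavelet)
  vals <- c(band_features(image, mask, ng, "native"),
            unlist(lapply(subband_order, function(sb)
              band_features(bands[[sb]]$image, bands[[sb]]$mask, ng, sb)),
              use.names = FALSE))
  names(vals) <- feature_inventory()
  vals
}

#' Select the CEUS peak-enhancement frame
#'
#' Among candidate frames, picks the one whose mean in-mask intensity is
#' largest (the time-intensity curve's peak); a single frame is returned
#' as-is.
#'
#' @param frames List of numeric matrices.
#' @param mask Logical ROI matrix.
#' @return The selected frame (numeric matrix).
#' @export
peak_frame <- function(frames, mask) {
  if (!is.list(frames)) return(frames)
  if (length(frames) == 1) return(frames[[1]])
  means <- vapply(frames, function(f) mean(f[mask]), numeric(1))
  frames[[which.max(means)]]
}

#' Extract features for every image record of a study
#'
#' @param images List of image records as produced by [gen_images()] (or
#'   assembled from [read_image_pair()]).
#' @param modality Which modality to tabulate (`"Bmode"` or `"CEUS-peak"`);
#'   `NULL` keeps all records.
#' @param ng,wavelet Passed to [extract_all()].
#' @return Data frame: `subject_id`, `group`, `modality`, then 368 feature
#'   columns named canonically.
#' @export
extract_table <- function(images, modality = NULL, ng = 32,
                          wavelet = "haar") {
  if (!is.null(modality))
    images <- Filter(function(r) r$modality == modality, images)
  if (!length(images)) stopf("no image records to extract")
  feats <- t(vapply(images, function(r)
    extract_all(r$image, r$mask, ng, wavelet),
    numeric(length(feature_inventory()))))
  meta <- data.frame(
    subject_id = vapply(images, `[[`, character(1), "subject_id"),
    group = vapply(images, function(r) r$group %||% NA_character_,
                   character(1)),
    modality = vapply(images, function(r) r$modality %||% NA_character_,
                      character(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats, check.names = FALSE))
}
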