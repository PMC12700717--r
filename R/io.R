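# Tabular and image IO. All tables are written with a header row and floats
# at 10 significant digits so that reruns with an identical seed are
# byte-identical.

format10 <- function(x) {
  if (is.double(x)) {
    out <- formatC(signif(x, 10), digits = 10, format = "g")
    out[is.na(x)] <- "NA"
    trimws(out)
  } else x
}

write_table10 <- function(df, path, sep = "\t") {
  out <- as.data.frame(lapply(df, format10), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

write_counts <- function(mat, path) {
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Read a counts matrix from TSV
#'
#' Expects a `feature_id` first column followed by one column per sample.
#'
#' @param path TSV file path.
#' @return Integer matrix, features x samples.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read time-intensity curves from CSV
#'
#' Expects columns `subject_id`, `t`, `intensity`; returns one curve per
#' subject in file order.
#'
#' @param path CSV file path.
#' @return List of lists with `subject_id`, `t`, `intensity`.
#' @export
read_tics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(unique(df$subject_id), function(id) {
    sub <- df[df$subject_id == id, ]
    list(subject_id = id, t = sub$t, intensity = sub$intensity)
  })
}

#' Read a grayscale image and its ROI mask from PNG
#'
#' @param image_path,mask_path PNG file paths; the mask is binarized at 0.5.
#' @return List with `image` (numeric matrix) and `mask` (logical matrix).
#' @export
read_image_pair <- function(image_path, mask_path) {
  img <- png::readPNG(image_path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  msk <- png::readPNG(mask_path)
  if (length(dim(msk)) == 3) msk <- msk[, , 1]
  list(image = img, mask = msk > 0.5)
}

#' Read gene-set collections in GMT format
#'
#' Each line: set name, description, then member ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}
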