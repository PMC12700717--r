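# Texture count structures built from a quantized ROI: gray-level
# co-occurrence (GLCM), run-length (GLRLM), size-zone (GLSZM) and
# neighborhood gray-tone difference (NGTDM). Out-of-mask pixels are NA and
# never contribute: co-occurring pairs with either pixel outside the mask
# are dropped, runs and zones break at the mask boundary, and neighborhood
# means are taken over in-mask neighbors only.

default_offsets <- function()
  list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))

#' Gray-level co-occurrence counts
#'
#' Counts of level pairs at the given pixel offsets, symmetrized (each pair
#' counted in both directions) and aggregated by summing over offsets.
#'
#' @param q A [quantize_roi()] result.
#' @param offsets List of integer `c(dr, dc)` offsets; default distance-1
#'   offsets at 0, 45, 90 and 135 degrees.
#' @return Ng x Ng symmetric count matrix.
#' @export
glcm_matrix <- function(q, offsets = default_offsets()) {
  if (!length(offsets)) stopf("offsets must be nonempty")
  L <- q$levels; ng <- q$ng
  nr <- nrow(L); nc <- ncol(L)
  G <- matrix(0, ng, ng)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rr <- seq(max(1, 1 - dr), min(nr, nr - dr))
    cc <- seq(max(1, 1 - dc), min(nc, nc - dc))
    if (!length(rr) || !length(cc)) next
    a <- L[rr, cc, drop = FALSE]
    b <- L[rr + dr, cc + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    t1 <- table(factor(a[ok], seq_len(ng)), factor(b[ok], seq_len(ng)))
    G <- G + t1 + t(t1)
  }
  unname(G)
}

# split the level matrix into colinear lines for one run direction
direction_lines <- function(L, dir) {
  switch(dir,
         "0" = split(L, row(L)),
         "90" = split(L, col(L)),
         "45" = split(L, row(L) + col(L)),
         "135" = split(L, row(L) - col(L)),
         stopf("unknown direction '%s'", dir))
}

# maximal same-level runs along one line; NA breaks runs
line_runs <- function(v) {
  enc <- ifelse(is.na(v), 0L, v)
  r <- rle(enc)
  keep <- r$values > 0L
  cbind(level = r$values[keep], length = r$lengths[keep])
}

#' Gray-level run-length counts
#'
#' Runs are maximal colinear in-mask segments of equal level, counted over
#' the given directions (counts summed across directions).
#'
#' @param q A [quantize_roi()] result.
#' @param directions Character subset of `c("0", "45", "90", "135")`.
#' @return Ng x Rmax count matrix (Rmax = longest observed run).
#' @export
glrlm_matrix <- function(q, directions = c("0", "45", "90", "135")) {
  if (!any(q$mask)) stopf("empty mask")
  runs <- do.call(rbind, lapply(directions, function(d) {
    do.call(rbind, lapply(direction_lines(q$levels, d), line_runs))
  }))
  rmax <- max(runs[, "length"])
  M <- matrix(0, q$ng, rmax)
  for (i in seq_len(nrow(runs)))
    M[runs[i, "level"], runs[i, "length"]] <-
      M[runs[i, "level"], runs[i, "length"]] + 1
  M
}

# 8-connected zone labeling via row runs + union-find; returns one row per
# zone: (level, size)
zone_sizes <- function(L) {
  nr <- nrow(L)
  run_rows <- vector("list", nr)
  nrun <- 0L
  for (i in seq_len(nr)) {
    r <- rle(ifelse(is.na(L[i, ]), 0L, L[i, ]))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values > 0L
    if (any(keep)) {
      rr <- cbind(level = r$values[keep], start = starts[keep],
                  end = ends[keep], id = nrun + seq_len(sum(keep)))
      nrun <- nrun + sum(keep)
      run_rows[[i]] <- rr
    }
  }
  if (nrun == 0L) return(cbind(level = integer(0), size = integer(0)))
  parent <- seq_len(nrun)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nr - 1L)) {
    a <- run_rows[[i]]; b <- run_rows[[i + 1L]]
    if (is.null(a) || is.null(b)) next
    for (j in seq_len(nrow(a))) {
      # 8-connectivity: column ranges may touch diagonally (+/- 1)
      hit <- which(b[, "level"] == a[j, "level"] &
                     b[, "start"] <= a[j, "end"] + 1L &
                     b[, "end"] >= a[j, "start"] - 1L)
      for (k in hit) {
        ra <- find(a[j, "id"]); rb <- find(b[k, "id"])
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  allruns <- do.call(rbind, run_rows)
  root <- vapply(allruns[, "id"], find, integer(1))
  len <- allruns[, "end"] - allruns[, "start"] + 1L
  size <- tapply(len, root, sum)
  lev <- tapply(allruns[, "level"], root, function(x) x[1])
  cbind(level = as.integer(lev), size = as.integer(size))
}

#' Gray-level size-zone counts
#'
#' Zones are 8-connected in-mask components of equal level.
#'
#' @param q A [quantize_roi()] result.
#' @return Ng x Zmax count matrix (Zmax = largest observed zone).
#' @export
glszm_matrix <- function(q) {
  if (!any(q$mask)) stopf("empty mask")
  z <- zone_sizes(q$levels)
  zmax <- max(z[, "size"])
  M <- matrix(0, q$ng, zmax)
  for (i in seq_len(nrow(z)))
    M[z[i, "level"], z[i, "size"]] <- M[z[i, "level"], z[i, "size"]] + 1
  M
}

#' Neighborhood gray-tone difference table
#'
#' For each level i present in the ROI: `n_i`, the number of in-mask pixels
#' of level i that have at least one in-mask 8-neighbor, and `s_i`, the sum
#' over those pixels of `|i - mean(in-mask 8-neighbor levels)|`.
#'
#' @param q A [quantize_roi()] result.
#' @return List with numeric vectors `n` and `s` of length Ng.
#' @export
ngtdm_table <- function(q) {
  if (!any(q$mask)) stopf("empty mask")
  L <- q$levels
  m <- !is.na(L)
  Lz <- L; Lz[!m] <- 0L
  nr <- nrow(L); nc <- ncol(L)
  S <- matrix(0, nr, nc); C <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sr <- seq(max(1, 1 - dr), min(nr, nr - dr))
    sc <- seq(max(1, 1 - dc), min(nc, nc - dc))
    S[sr, sc] <- S[sr, sc] + Lz[sr + dr, sc + dc, drop = FALSE]
    C[sr, sc] <- C[sr, sc] + m[sr + dr, sc + dc, drop = FALSE]
  }
  valid <- m & C > 0
  lev <- L[valid]
  diffs <- abs(lev - S[valid] / C[valid])
  s <- as.numeric(tapply(diffs, factor(lev, seq_len(q$ng)), sum))
  s[is.na(s)] <- 0
  list(n = tabulate(lev, q$ng), s = s)
}
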