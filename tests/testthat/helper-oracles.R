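# Independent brute-force oracles. Everything here enumerates pixels,
# pairs, runs, zones or score vectors with plain loops, sharing no code
# with the package implementation.

# ---- texture matrices ------------------------------------------------

oracle_glcm <- function(levels, ng, offsets) {
  G <- matrix(0, ng, ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (off in offsets) {
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      i2 <- i + off[1]; j2 <- j + off[2]
      if (i2 < 1 || i2 > nr || j2 < 1 || j2 > nc) next
      a <- levels[i, j]; b <- levels[i2, j2]
      if (is.na(a) || is.na(b)) next
      G[a, b] <- G[a, b] + 1
      G[b, a] <- G[b, a] + 1
    }
  }
  G
}

# walk every line of a direction pixel by pixel, recording maximal runs
oracle_runs <- function(levels, dirs) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- list("0" = c(0, 1), "90" = c(1, 0), "45" = c(-1, 1),
               "135" = c(1, 1))
  out <- NULL
  for (d in dirs) {
    s <- step[[d]]
    starts <- NULL
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      pi <- i - s[1]; pj <- j - s[2]
      if (pi < 1 || pi > nr || pj < 1 || pj > nc)
        starts <- rbind(starts, c(i, j))
    }
    for (k in seq_len(nrow(starts))) {
      i <- starts[k, 1]; j <- starts[k, 2]
      cur <- NA; len <- 0
      while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
        v <- levels[i, j]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1
        } else {
          if (!is.na(cur)) out <- rbind(out, c(cur, len))
          cur <- v; len <- if (is.na(v)) 0 else 1
        }
        i <- i + s[1]; j <- j + s[2]
      }
      if (!is.na(cur)) out <- rbind(out, c(cur, len))
    }
  }
  out
}

oracle_glrlm <- function(levels, ng, dirs) {
  runs <- oracle_runs(levels, dirs)
  M <- matrix(0, ng, max(runs[, 2]))
  for (k in seq_len(nrow(runs)))
    M[runs[k, 1], runs[k, 2]] <- M[runs[k, 1], runs[k, 2]] + 1
  M
}

# BFS flood fill, 8-connected, equal level
oracle_zones <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  zones <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (seen[i, j] || is.na(levels[i, j])) next
    lev <- levels[i, j]
    queue <- list(c(i, j)); seen[i, j] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        a <- p[1] + di; b <- p[2] + dj
        if (a < 1 || a > nr || b < 1 || b > nc) next
        if (seen[a, b] || is.na(levels[a, b]) || levels[a, b] != lev) next
        seen[a, b] <- TRUE
        queue[[length(queue) + 1]] <- c(a, b)
      }
    }
    zones <- rbind(zones, c(lev, size))
  }
  zones
}

oracle_glszm <- function(levels, ng) {
  z <- oracle_zones(levels)
  M <- matrix(0, ng, max(z[, 2]))
  for (k in seq_len(nrow(z)))
    M[z[k, 1], z[k, 2]] <- M[z[k, 1], z[k, 2]] + 1
  M
}

oracle_ngtdm <- function(levels, ng) {
  nr <- nrow(levels); nc <- ncol(levels)
  n <- numeric(ng); s <- numeric(ng)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- levels[i, j]
    if (is.na(v)) next
    nb <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      a <- i + di; b <- j + dj
      if (a < 1 || a > nr || b < 1 || b > nc) next
      if (!is.na(levels[a, b])) nb <- c(nb, levels[a, b])
    }
    if (!length(nb)) next
    n[v] <- n[v] + 1
    s[v] <- s[v] + abs(v - mean(nb))
  }
  list(n = n, s = s)
}

# ---- feature formulas on oracle matrices (plain double loops) --------

oracle_rl_sz <- function(M, npix) {
  nruns <- sum(M)
  ng <- nrow(M); kmax <- ncol(M)
  sre <- lre <- lg <- hg <- slg <- shg <- llg <- lhg <- 0
  mu_i <- mu_k <- 0
  for (i in seq_len(ng)) for (k in seq_len(kmax)) {
    p <- M[i, k] / nruns
    sre <- sre + p / k^2; lre <- lre + p * k^2
    lg <- lg + p / i^2; hg <- hg + p * i^2
    slg <- slg + p / (i^2 * k^2); shg <- shg + p * i^2 / k^2
    llg <- llg + p * k^2 / i^2; lhg <- lhg + p * i^2 * k^2
    mu_i <- mu_i + p * i; mu_k <- mu_k + p * k
  }
  glv <- rlv <- 0
  for (i in seq_len(ng)) for (k in seq_len(kmax)) {
    p <- M[i, k] / nruns
    glv <- glv + p * (i - mu_i)^2
    rlv <- rlv + p * (k - mu_k)^2
  }
  c(sum(rowSums(M)^2) / nruns, sum(colSums(M)^2) / nruns, nruns / npix,
    sre, lre, lg, hg, slg, shg, llg, lhg, glv, rlv)
}

oracle_glcm_features <- function(G) {
  P <- G / sum(G)
  ng <- nrow(P)
  mu <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) mu <- mu + i * P[i, j]
  va <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) va <- va + (i - mu)^2 * P[i, j]
  energy <- contrast <- corr <- hom <- ent <- savg <- dis <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    p <- P[i, j]
    energy <- energy + p^2
    contrast <- contrast + (i - j)^2 * p
    hom <- hom + p / (1 + (i - j)^2)
    if (p > 0) ent <- ent - p * log2(p)
    savg <- savg + (i + j) * p
    dis <- dis + abs(i - j) * p
    if (va > 0) corr <- corr + (i - mu) * (j - mu) * p / va
  }
  c(Energy = energy, Contrast = contrast, Correlation = corr,
    Homogeneity = hom, Entropy = ent, Variance = va, SumAverage = savg,
    Dissimilarity = dis, MaxProbability = max(P))
}

oracle_ngtdm_features <- function(tb, ng, cap = 1e6) {
  n <- tb$n; s <- tb$s
  N <- sum(n); p <- n / N
  pres <- which(p > 0); ngp <- length(pres)
  den <- sum(p * s)
  coarse <- if (den == 0) cap else 1 / den
  contrast <- busy <- cplx <- strength <- 0
  if (ngp > 1) {
    cc <- 0
    for (i in pres) for (j in pres) cc <- cc + p[i] * p[j] * (i - j)^2
    contrast <- cc / (ngp * (ngp - 1)) * sum(s) / N
    bd <- 0
    for (i in pres) for (j in pres) bd <- bd + abs(i * p[i] - j * p[j])
    busy <- if (bd == 0) 0 else den / bd
    for (i in pres) for (j in pres)
      cplx <- cplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
        (N * (p[i] + p[j]))
    sd_ <- 0
    for (i in pres) for (j in pres) sd_ <- sd_ + (p[i] + p[j]) * (i - j)^2
    strength <- if (sum(s) == 0) 0 else sd_ / sum(s)
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = cplx, Strength = strength)
}

# ---- selection, AUC --------------------------------------------------

# exhaustive greedy oracle recomputing all correlations at every step
oracle_select <- function(x, labels, drop_ratio = 0.5, max_features = 20) {
  x <- as.data.frame(x)
  y <- as.numeric(as.factor(labels)) - 1
  safe_cor <- function(a, b)
    if (sd(a) == 0 || sd(b) == 0) 0 else abs(cor(a, b))
  feats <- sort(colnames(x))
  selected <- character(0); scores <- numeric(0)
  prev <- NA
  repeat {
    cand <- setdiff(feats, selected)
    if (!length(cand)) return(list(selected = selected, score = scores,
                                   reason = "exhausted"))
    best <- NA; best_crit <- -Inf
    for (f in cand) {
      rel <- safe_cor(x[[f]], y)
      red <- if (!length(selected)) 0 else
        mean(sapply(selected, function(g) safe_cor(x[[f]], x[[g]])))
      crit <- rel - red
      # cand is scanned in sorted order, so keeping strict improvements
      # implements the lexicographic tie-break
      if (crit > best_crit) {
        best <- f; best_crit <- crit
      }
    }
    rel <- safe_cor(x[[best]], y)
    red <- if (!length(selected)) 0 else
      mean(sapply(selected, function(g) safe_cor(x[[best]], x[[g]])))
    score <- rel + red
    if (length(selected) >= 1 && score < drop_ratio * prev)
      return(list(selected = selected, score = scores,
                  reason = "score_drop"))
    selected <- c(selected, best); scores <- c(scores, score)
    prev <- score
    if (length(selected) >= max_features)
      return(list(selected = selected, score = scores,
                  reason = "max_features"))
  }
}

# AUC by exhaustive positive-negative pair counting
oracle_auc <- function(scores, labels) {
  y <- as.numeric(as.factor(labels)) - 1
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# ---- shared fixtures -------------------------------------------------

random_quantized <- function(nr, nc, ng, mask_frac = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lev <- matrix(sample(seq_len(ng), nr * nc, replace = TRUE), nr, nc)
  mask <- matrix(runif(nr * nc) < mask_frac, nr, nc)
  if (!any(mask)) mask[1, 1] <- TRUE
  lev[!mask] <- NA
  structure(list(levels = lev, ng = as.integer(ng), mask = mask),
            class = "quantized_roi")
}

tiny_study_config <- function(seed = 1, ...) {
  args <- list(n_healthy = 5, n_T2c = 6, n_T3b = 5, image_size = 64,
               n_mrna = 250, n_mirna = 80, n_planted_de = 12,
               n_mirna_planted_de = 6, seed = seed)
  do.call(study_config, utils::modifyList(args, list(...)))
}
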