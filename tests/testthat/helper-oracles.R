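# Independent brute-force oracles. These deliberately share no code with the
# package implementation: explicit loops, naive recomputation.

# Pair-enumeration co-occurrence: loop over every pixel, count the pair at
# the given shift if in bounds.
oracle_cooccurrence <- function(levels, shift, n_gray, symmetric = TRUE) {
  counts <- matrix(0, n_gray, n_gray)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + shift[1]; c2 <- c + shift[2]
      if (r2 >= 1 && r2 <= nrow(levels) && c2 >= 1 && c2 <= ncol(levels)) {
        a <- levels[r, c] + 1; b <- levels[r2, c2] + 1
        counts[a, b] <- counts[a, b] + 1
        if (symmetric) counts[b, a] <- counts[b, a] + 1
      }
    }
  }
  counts / sum(counts)
}

# Direct formula evaluation of the seven statistics with explicit loops.
oracle_glcm_stats <- function(P) {
  n <- nrow(P)
  mu <- va <- ct <- ds <- hm <- sm <- en <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    i <- a - 1; j <- b - 1; p <- P[a, b]
    mu <- mu + i * p
  }
  for (a in seq_len(n)) for (b in seq_len(n)) {
    i <- a - 1; j <- b - 1; p <- P[a, b]
    va <- va + (i - mu)^2 * p
    ct <- ct + (i - j)^2 * p
    ds <- ds + abs(i - j) * p
    hm <- hm + p / (1 + (i - j)^2)
    sm <- sm + p^2
    if (p > 0) en <- en - p * log(p)
  }
  c(mean = mu, variance = va, contrast = ct, dissimilarity = ds,
    homogeneity = hm, second_moment = sm, entropy = en)
}

# Independent equal-width quantizer (same definition, separate code).
oracle_quantize <- function(x, n_gray) {
  lo <- min(x); hi <- max(x)
  if (lo == hi) return(matrix(0, nrow(x), ncol(x)))
  q <- floor((x - lo) / (hi - lo) * n_gray)
  q[q > n_gray - 1] <- n_gray - 1
  q
}

# Moving-window texture oracle: for each interior pixel, enumerate all pair
# positions inside the window for every shift, pool counts, evaluate stats.
oracle_texture_map <- function(tile, n_gray = 4, window = 3,
                               shifts = list(c(0, 1), c(-1, 1), c(-1, 0),
                                             c(-1, -1)),
                               symmetric = TRUE) {
  lv <- oracle_quantize(tile, n_gray)
  h <- nrow(tile); w <- ncol(tile); m <- (window - 1) / 2
  stat_names <- c("mean", "variance", "contrast", "dissimilarity",
                  "homogeneity", "second_moment", "entropy")
  maps <- lapply(stat_names, function(s) matrix(NA_real_, h, w))
  names(maps) <- stat_names
  for (ci in (m + 1):(h - m)) {
    for (cj in (m + 1):(w - m)) {
      counts <- matrix(0, n_gray, n_gray)
      for (s in shifts) {
        for (r in (ci - m):(ci + m)) {
          for (c in (cj - m):(cj + m)) {
            r2 <- r + s[1]; c2 <- c + s[2]
            if (r2 >= ci - m && r2 <= ci + m &&
                c2 >= cj - m && c2 <= cj + m) {
              a <- lv[r, c] + 1; b <- lv[r2, c2] + 1
              counts[a, b] <- counts[a, b] + 1
              if (symmetric) counts[b, a] <- counts[b, a] + 1
            }
          }
        }
      }
      st <- oracle_glcm_stats(counts / sum(counts))
      for (nm in stat_names) maps[[nm]][ci, cj] <- st[nm]
    }
  }
  maps
}

# Naive O(n^3) UPGMA returning the cophenetic distance matrix: clusters are
# merged at the smallest average cross-pair distance, recomputed from the
# original distances at every step.
oracle_upgma_cophenetic <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        pairs <- expand.grid(clusters[[i]], clusters[[j]])
        avg <- mean(dm[cbind(pairs[[1]], pairs[[2]])])
        if (avg < bestd) { bestd <- avg; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    for (x in a) for (y in b) { coph[x, y] <- bestd; coph[y, x] <- bestd }
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Shared fixture: study-condition simulator configs for the three
# tissue-pattern groups (sparse/dense dispersed, clustered dense).
pattern_group_config <- function(kind, seed) {
  switch(kind,
         sparse = histology_sim_config(cell_count = 250, seed = seed),
         dense = histology_sim_config(cell_count = 1250, seed = seed),
         clustered = histology_sim_config(cell_count = 1250,
                                          clustering_mode = "clustered",
                                          cluster_count = 6,
                                          cluster_sd_px = 40, seed = seed))
}

# Full image -> features pipeline for one simulated image.
pipeline_features <- function(cfg, group) {
  sim <- simulate_histology(cfg)
  norm <- suppressMessages(normalize_background(sim$image))
  tiles <- filter_tiles(tile_roi(norm), norm)
  if (sum(tiles$tiles$keep) == 0L) return(NULL)
  tf <- texture_features(norm, tiles)
  tf$group <- group
  tf
}
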