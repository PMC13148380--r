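# Gray-level co-occurrence matrix (GLCM) texture engine: per-tile
# quantization, co-occurrence estimation, the seven Haralick-style
# statistics, moving-window texture maps and per-tile summary features.
#
# The moving-window maps are computed with summed-area tables: for each shift
# and each (level_i, level_j) pair code, the count of co-occurring pairs
# inside every window is a box sum over an indicator image, so the whole map
# is obtained without an explicit per-pixel loop.

.glcm_statistics <- c("mean", "variance", "contrast", "dissimilarity",
                      "homogeneity", "second_moment", "entropy")
.tile_summaries <- c("mean", "sd", "q1", "q3", "kurtosis", "skewness")

#' GLCM configuration
#'
#' @param n_gray number of gray levels after quantization (default 4).
#' @param window odd moving-window side in pixels (default 3).
#' @param shifts list of `(drow, dcol)` integer offsets; the default is the
#'   four standard angles 0 = `(0, 1)`, 45 = `(-1, 1)`, 90 = `(-1, 0)`,
#'   135 = `(-1, -1)`.
#' @param statistics which statistics to compute (default all seven).
#' @param symmetric count each pair in both directions (default `TRUE`).
#' @param log_base base of the entropy logarithm: `"natural"` or `"log2"`.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(n_gray = 4L, window = 3L,
                        shifts = list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L),
                                      c(-1L, -1L)),
                        statistics = .glcm_statistics,
                        symmetric = TRUE,
                        log_base = c("natural", "log2")) {
  log_base <- match.arg(log_base)
  statistics <- match.arg(statistics, .glcm_statistics, several.ok = TRUE)
  n_gray <- as.integer(n_gray); window <- as.integer(window)
  stopifnot(n_gray >= 2L, window >= 3L, window %% 2L == 1L,
            length(shifts) >= 1L)
  for (s in shifts) stopifnot(length(s) == 2L)
  structure(list(n_gray = n_gray, window = window,
                 shifts = lapply(shifts, as.integer),
                 statistics = statistics, symmetric = symmetric,
                 log_base = log_base),
            class = "glcm_config")
}

#' Quantize a tile into equal-width gray levels
#'
#' Bins span the observed range of the tile:
#' `level = min(floor((x - min) / (max - min) * n_gray), n_gray - 1)`.
#' A constant tile maps to level 0 everywhere. Quantization is performed once
#' per tile (not per window), so level identities are stable across the tile.
#'
#' @param pixels numeric matrix.
#' @param n_gray number of levels.
#' @return Integer matrix with values in `0:(n_gray - 1)`.
#' @export
quantize <- function(pixels, n_gray = 4L) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), n_gray >= 2L)
  rng <- range(pixels)
  if (rng[1] == rng[2]) {
    lv <- matrix(0L, nrow(pixels), ncol(pixels))
  } else {
    lv <- floor((pixels - rng[1]) / (rng[2] - rng[1]) * n_gray)
    lv[lv > n_gray - 1L] <- n_gray - 1L
    storage.mode(lv) <- "integer"
  }
  lv
}

#' Co-occurrence probability matrix for one shift
#'
#' Counts pairs `(levels[r, c], levels[r + drow, c + dcol])` over all
#' in-bounds positions; if `symmetric`, the transpose counts are added; the
#' matrix is normalized to sum to 1.
#'
#' @param levels integer matrix of gray levels in `0:(n_gray - 1)`.
#' @param shift integer `(drow, dcol)` offset.
#' @param n_gray number of gray levels (matrix dimension).
#' @param symmetric add transpose counts (default `TRUE`).
#' @return An `n_gray` x `n_gray` probability matrix.
#' @export
cooccurrence <- function(levels, shift, n_gray = 4L, symmetric = TRUE) {
  stopifnot(is.matrix(levels), length(shift) == 2L)
  dr <- as.integer(shift[1L]); dc <- as.integer(shift[2L])
  h <- nrow(levels); w <- ncol(levels)
  r0 <- max(1L, 1L - dr); r1 <- min(h, h - dr)
  c0 <- max(1L, 1L - dc); c1 <- min(w, w - dc)
  if (r0 > r1 || c0 > c1)
    stop("no pixel pairs: image too small for shift (", dr, ", ", dc, ")",
         call. = FALSE)
  a <- levels[r0:r1, c0:c1, drop = FALSE]
  b <- levels[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
  counts <- matrix(tabulate(a * n_gray + b + 1L, nbins = n_gray * n_gray),
                   n_gray, n_gray, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

#' Haralick-style statistics of a co-occurrence matrix
#'
#' With `P(i, j)` indexed by 0-based gray levels:
#' mean `mu = sum(i * P)`; variance `sum((i - mu)^2 * P)`;
#' contrast `sum((i - j)^2 * P)`; dissimilarity `sum(|i - j| * P)`;
#' homogeneity `sum(P / (1 + (i - j)^2))`; second moment `sum(P^2)`;
#' entropy `-sum(P * log(P))` with `0 * log 0 = 0`.
#'
#' @param P co-occurrence probability matrix (sums to 1).
#' @param log_base `"natural"` (default) or `"log2"` entropy logarithm.
#' @return Named numeric vector of the seven statistics.
#' @export
glcm_statistics <- function(P, log_base = c("natural", "log2")) {
  log_base <- match.arg(log_base)
  stopifnot(is.matrix(P), nrow(P) == ncol(P),
            abs(sum(P) - 1) < 1e-8)
  n <- nrow(P)
  i <- matrix(rep(0:(n - 1L), n), n, n)      # row level
  j <- t(i)                                   # col level
  mu <- sum(i * P)
  lg <- if (log_base == "natural") log else log2
  plogp <- ifelse(P > 0, P * lg(P), 0)
  c(mean = mu,
    variance = sum((i - mu)^2 * P),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    homogeneity = sum(P / (1 + (i - j)^2)),
    second_moment = sum(P^2),
    entropy = -sum(plogp))
}

#' Moving-window GLCM texture maps
#'
#' Quantizes the whole tile once, then for every pixel whose
#' `window` x `window` neighborhood is complete, accumulates co-occurrence
#' counts over all configured shifts into one pooled matrix per window
#' (pair counts added at the count level, transposed when symmetric) and
#' computes the configured statistics. Border pixels with an incomplete
#' window are `NA`.
#'
#' @param pixels numeric matrix (an aggregated tile).
#' @param config a [glcm_config()].
#' @param pool_shifts pool all shifts into one co-occurrence per window
#'   (default, matching multi-shift texture packages). With `FALSE` a list of
#'   per-shift texture maps is returned for diagnostics.
#' @return An object of class `texture_map`: list with `maps` (named list of
#'   matrices, same shape as `pixels`), logical `valid` mask, and the
#'   `config`. For `pool_shifts = FALSE`, a list of such objects, one per
#'   shift.
#' @export
texture_map <- function(pixels, config = glcm_config(), pool_shifts = TRUE) {
  stopifnot(inherits(config, "glcm_config"), is.matrix(pixels))
  h <- nrow(pixels); w <- ncol(pixels)
  win <- config$window
  if (h < win || w < win)
    stop("tile (", h, "x", w, ") is smaller than the window (", win, ")",
         call. = FALSE)
  if (!pool_shifts) {
    out <- lapply(config$shifts, function(s) {
      cfg1 <- config; cfg1$shifts <- list(s)
      texture_map(pixels, cfg1, pool_shifts = TRUE)
    })
    names(out) <- vapply(config$shifts,
                         function(s) paste0(s, collapse = ","), "")
    return(out)
  }
  ng <- config$n_gray
  lv <- quantize(pixels, ng)
  m <- (win - 1L) %/% 2L
  oh <- h - 2L * m; ow <- w - 2L * m
  ncode <- ng * ng
  counts <- array(0, dim = c(oh, ow, ncode))
  for (s in config$shifts) {
    dr <- s[1L]; dc <- s[2L]
    if (abs(dr) >= win || abs(dc) >= win)
      stop("no pixel pairs: window too small for shift (", dr, ", ", dc,
           ")", call. = FALSE)
    r0 <- max(1L, 1L - dr); r1 <- min(h, h - dr)
    c0 <- max(1L, 1L - dc); c1 <- min(w, w - dc)
    code <- lv[r0:r1, c0:c1, drop = FALSE] * ng +
      lv[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
    bh <- win - abs(dr); bw <- win - abs(dc)
    for (k in 0:(ncode - 1L)) {
      counts[, , k + 1L] <- counts[, , k + 1L] +
        boxsum(code == k, bh, bw)
    }
  }
  if (config$symmetric) {
    ci <- rep(0:(ng - 1L), each = ng)   # row level of code (0-based, code = i*ng + j)
    cj <- rep(0:(ng - 1L), times = ng)
    tcode <- cj * ng + ci               # transposed code
    counts <- counts + counts[, , tcode + 1L, drop = FALSE]
  }
  Pm <- matrix(counts, nrow = oh * ow, ncol = ncode)
  tot <- rowSums(Pm)
  Pm <- Pm / tot
  iv <- rep(0:(ng - 1L), each = ng)
  jv <- rep(0:(ng - 1L), times = ng)
  dd <- iv - jv
  lg <- if (config$log_base == "natural") log else log2
  vals <- list()
  mu <- as.vector(Pm %*% iv)
  if ("mean" %in% config$statistics) vals$mean <- mu
  if ("variance" %in% config$statistics)
    vals$variance <- as.vector(Pm %*% (iv^2)) - mu^2
  if ("contrast" %in% config$statistics)
    vals$contrast <- as.vector(Pm %*% (dd^2))
  if ("dissimilarity" %in% config$statistics)
    vals$dissimilarity <- as.vector(Pm %*% abs(dd))
  if ("homogeneity" %in% config$statistics)
    vals$homogeneity <- as.vector(Pm %*% (1 / (1 + dd^2)))
  if ("second_moment" %in% config$statistics)
    vals$second_moment <- rowSums(Pm^2)
  if ("entropy" %in% config$statistics) {
    pl <- Pm * lg(Pm)
    pl[Pm == 0] <- 0
    vals$entropy <- -rowSums(pl)
  }
  valid <- matrix(FALSE, h, w)
  valid[(m + 1L):(h - m), (m + 1L):(w - m)] <- TRUE
  maps <- lapply(vals[config$statistics[config$statistics %in% names(vals)]],
                 function(v) {
                   full <- matrix(NA_real_, h, w)
                   full[(m + 1L):(h - m), (m + 1L):(w - m)] <- v
                   full
                 })
  structure(list(maps = maps, valid = valid, config = config),
            class = "texture_map")
}

#' @export
print.texture_map <- function(x, ...) {
  cat(sprintf("texture_map: %s; %d valid pixels of %s\n",
              paste(names(x$maps), collapse = ", "),
              sum(x$valid), paste(dim(x$valid), collapse = "x")))
  invisible(x)
}

#' Summarize texture maps into a per-tile feature vector
#'
#' For each statistic map, computes six summaries over unmasked pixels:
#' mean, sample standard deviation (`n - 1`), first and third quartiles
#' (type-7 linear interpolation), excess kurtosis and moment skewness `g1`
#' (both via \pkg{e1071}, type 1). Degenerate maps (zero variance or fewer
#' than 2 valid pixels) yield `NaN` for sd-based summaries and are flagged.
#'
#' @param tm a [texture_map()].
#' @param tile_id identifier stored with the feature vector.
#' @return A one-row data frame with `tile_id`, `n_valid_pixels`, a logical
#'   `flagged` column (any `NaN` summaries), and one column per
#'   statistic-summary pair named `<statistic>_<summary>` (42 columns for the
#'   full statistic set).
#' @export
summarize_tile <- function(tm, tile_id = NA) {
  stopifnot(inherits(tm, "texture_map"))
  nv <- sum(tm$valid)
  if (nv < 1L) stop("all pixels are masked; nothing to summarize",
                    call. = FALSE)
  out <- list(tile_id = tile_id, n_valid_pixels = nv)
  flagged <- FALSE
  for (stat in names(tm$maps)) {
    v <- tm$maps[[stat]][tm$valid]
    s <- if (nv >= 2L) sd(v) else NaN
    qs <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    if (is.na(s) || s == 0) {
      kur <- NaN; ske <- NaN
    } else {
      kur <- e1071::kurtosis(v, type = 1)
      ske <- e1071::skewness(v, type = 1)
    }
    vals <- c(mean(v), s, qs[1], qs[2], kur, ske)
    flagged <- flagged || any(is.nan(vals))
    out[paste0(stat, "_", .tile_summaries)] <- as.list(vals)
  }
  out$flagged <- flagged
  as.data.frame(out, check.names = FALSE)
}

#' Per-tile texture features for all kept tiles
#'
#' Runs the texture stage of the pipeline for every kept tile of a filtered
#' tile set: extract tile pixels, aggregate by `block` x `block` averaging,
#' compute moving-window texture maps, and summarize into the 42-feature
#' vector. Metadata columns identify each tile.
#'
#' @param image the (normalized) grayscale matrix.
#' @param tiles a filtered [tile_roi()] result.
#' @param config a [glcm_config()].
#' @param block aggregation block size before texture (default 3).
#' @return A data frame with one row per kept tile: `tile_id`, `row_idx`,
#'   `col_idx`, `n_valid_pixels`, `flagged`, and 42 feature columns.
#' @export
texture_features <- function(image, tiles, config = glcm_config(),
                             block = 3L) {
  stopifnot(inherits(tiles, "tile_set"))
  check_image(image)
  kept <- which(tiles$tiles$keep)
  rows <- vector("list", length(kept))
  for (n in seq_along(kept)) {
    tr <- tiles$tiles[kept[n], ]
    px <- aggregate_tile(tile_pixels(image, tr), block = block)
    tm <- texture_map(px, config)
    fv <- summarize_tile(tm, tile_id = sprintf("r%d_c%d", tr$row_idx,
                                               tr$col_idx))
    fv$row_idx <- tr$row_idx; fv$col_idx <- tr$col_idx
    rows[[n]] <- fv
  }
  out <- do.call(rbind, rows)
  meta <- c("tile_id", "row_idx", "col_idx", "n_valid_pixels", "flagged")
  out[, c(meta, setdiff(names(out), meta))]
}

#' Names of the 42 texture feature columns
#'
#' @return Character vector `<statistic>_<summary>` over the seven GLCM
#'   statistics and six tile summaries.
#' @export
texture_feature_names <- function() {
  as.vector(t(outer(.glcm_statistics, .tile_summaries, paste, sep = "_")))
}
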