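# Internal numeric helpers shared across modules.

# Round half away from zero (base round() is round-half-to-even).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Column-wise cumulative sums via one whole-vector cumsum (column-major
# storage) with per-column offset correction; avoids apply() overhead.
col_cumsum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  cs <- matrix(cumsum(m), h, w)
  if (w > 1L) cs <- cs - rep(c(0, cs[h, -w]), each = h)
  cs
}

# Cumulative-sum (summed-area) box filter: sums of all `bh` x `bw` windows of
# `m`, returned as an (nrow - bh + 1) x (ncol - bw + 1) matrix. Used to count
# co-occurring pixel pairs inside every moving window in one vectorized pass.
boxsum <- function(m, bh, bw) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(bh >= 1L, bw >= 1L, bh <= h, bw <= w)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- t(col_cumsum(t(col_cumsum(m))))
  S[(bh + 1L):(h + 1L), (bw + 1L):(w + 1L), drop = FALSE] -
    S[1L:(h - bh + 1L), (bw + 1L):(w + 1L), drop = FALSE] -
    S[(bh + 1L):(h + 1L), 1L:(w - bw + 1L), drop = FALSE] +
    S[1L:(h - bh + 1L), 1L:(w - bw + 1L), drop = FALSE]
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_image <- function(pixels, arg = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop(arg, " must be at least 2x2", call. = FALSE)
  if (anyNA(pixels))
    stop(arg, " contains NA/NaN values", call. = FALSE)
  if (min(pixels) < 0)
    stop(arg, " contains negative intensities", call. = FALSE)
  invisible(pixels)
}
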