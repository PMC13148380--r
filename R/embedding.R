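# PCA embedding of tile-level texture features: feature-matrix assembly,
# prcomp-based PCA with a deterministic sign convention, and a tile-thumbnail
# scatter of the first two components.

utils::globalVariables(c("PC1", "PC2"))

#' Assemble a tile x feature matrix from texture feature tables
#'
#' Binds one or more [texture_features()] tables, keeps the numeric feature
#' columns, and drops rows containing flagged `NaN` summaries (degenerate
#' tiles), reporting how many were removed. Metadata columns are preserved as
#' row annotations.
#'
#' @param ... texture feature data frames (or a single list of them); each
#'   may carry extra metadata columns such as `sample` or `condition`.
#' @return A list with `x` (numeric matrix, tiles x features) and `meta`
#'   (data frame of non-feature columns, same row order).
#' @export
feature_matrix <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) &&
      !is.data.frame(tabs[[1L]])) tabs <- tabs[[1L]]
  df <- do.call(rbind, tabs)
  feat_cols <- intersect(texture_feature_names(), names(df))
  if (length(feat_cols) < 2L)
    stop("fewer than 2 texture feature columns found", call. = FALSE)
  x <- as.matrix(df[, feat_cols])
  bad <- apply(x, 1L, function(r) any(!is.finite(r)))
  if (any(bad))
    message(sprintf("feature_matrix: dropped %d / %d tiles with NaN features",
                    sum(bad), nrow(x)))
  if (sum(!bad) < 2L)
    stop("fewer than 2 usable tiles after NaN filtering", call. = FALSE)
  list(x = x[!bad, , drop = FALSE],
       meta = df[!bad, setdiff(names(df), feat_cols), drop = FALSE])
}

#' PCA of a tile x feature matrix
#'
#' Columns are centered and, by default, scaled to unit variance
#' (zero-variance columns are dropped with a warning); components come from
#' the SVD via [stats::prcomp()]. Scaling is on by default because the 42
#' texture summaries live on heterogeneous scales (entropies vs variances);
#' without it, variance-type features dominate the rotation. A deterministic
#' sign convention is applied: the largest-magnitude entry of each loading
#' column is positive.
#'
#' @param x numeric matrix (tiles x features) or a [feature_matrix()]
#'   result.
#' @param standardize scale columns to unit variance (default `TRUE`).
#' @return An object of class `pca_result`: `scores` (tiles x components),
#'   `loadings` (features x components), `explained_variance_ratio`,
#'   `center`, `scale`, `dropped_columns`.
#' @export
fit_pca <- function(x, standardize = TRUE) {
  meta <- NULL
  if (is.list(x) && !is.null(x$x)) { meta <- x$meta; x <- x$x }
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2L) stop("need at least 2 rows", call. = FALSE)
  v <- apply(x, 2L, var)
  dropped <- character()
  if (standardize && any(v == 0)) {
    dropped <- colnames(x)[v == 0]
    warning("dropping zero-variance columns before scaling: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    x <- x[, v > 0, drop = FALSE]
  }
  if (ncol(x) < 2L)
    stop("fewer than 2 usable feature columns", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = standardize)
  # deterministic sign: largest-|loading| entry of each column positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance_ratio = evr,
                 center = pc$center,
                 scale = if (standardize) pc$scale else NULL,
                 dropped_columns = dropped, meta = meta),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d tiles x %d features\n",
              nrow(x$scores), nrow(x$loadings)))
  cat("  explained variance (first 5): ",
      paste(sprintf("%.1f%%",
                    100 * head(x$explained_variance_ratio, 5L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select the most extreme tiles per PCA quadrant
#'
#' For each quadrant of the (PC1, PC2) plane, picks the `k` tiles furthest
#' from the origin. Used to choose which tile thumbnails to draw on the
#' embedding.
#'
#' @param pca a [fit_pca()] result.
#' @param k tiles per quadrant (default 3; clamped to availability).
#' @return Integer vector of row indices into `pca$scores`.
#' @export
select_extreme_tiles <- function(pca, k = 3L) {
  stopifnot(inherits(pca, "pca_result"), k >= 1L)
  s <- pca$scores
  quad <- paste0(ifelse(s[, 1L] >= 0, "+", "-"),
                 ifelse(s[, 2L] >= 0, "+", "-"))
  r2 <- s[, 1L]^2 + s[, 2L]^2
  idx <- unlist(lapply(split(seq_len(nrow(s)), quad), function(i) {
    i[order(r2[i], decreasing = TRUE)][seq_len(min(k, length(i)))]
  }), use.names = FALSE)
  sort(idx)
}

#' Scatter tiles in PCA space with image thumbnails
#'
#' Draws PC1/PC2 scores as points and overlays grayscale tile thumbnails for
#' a subset of tiles (the `k` most extreme per quadrant). Tiles whose
#' thumbnail is missing (`NULL`) are drawn as points only, with a warning.
#'
#' @param pca a [fit_pca()] result.
#' @param thumbnails optional list of numeric matrices in `[0, 1]`, one per
#'   tile (row of `pca$scores`), or `NULL` for a plain scatter.
#' @param k thumbnails per quadrant (default 3).
#' @param thumb_size thumbnail side length in score units.
#' @param color optional vector (length = tiles) mapped to point color.
#' @return A ggplot object.
#' @export
tile_scatter <- function(pca, thumbnails = NULL, k = 3L, thumb_size = NULL,
                         color = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  s <- as.data.frame(pca$scores[, 1:2, drop = FALSE])
  names(s) <- c("PC1", "PC2")
  if (!is.null(color)) s$color <- color
  p <- ggplot2::ggplot(s, ggplot2::aes(x = PC1, y = PC2)) +
    (if (is.null(color)) ggplot2::geom_point(alpha = 0.5)
     else ggplot2::geom_point(ggplot2::aes(color = color),
                              alpha = 0.7)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * pca$explained_variance_ratio[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * pca$explained_variance_ratio[2L]),
      color = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thumbnails)) {
    sel <- select_extreme_tiles(pca, k = k)
    if (is.null(thumb_size)) {
      thumb_size <- 0.08 * max(diff(range(s$PC1)), diff(range(s$PC2)))
    }
    half <- thumb_size / 2
    for (i in sel) {
      th <- if (i <= length(thumbnails)) thumbnails[[i]] else NULL
      if (is.null(th)) {
        warning("missing thumbnail for tile ", i, "; drawing point only",
                call. = FALSE)
        next
      }
      p <- p + ggplot2::annotation_raster(
        grDevices::as.raster(pmin(pmax(th, 0), 1)),
        xmin = s$PC1[i] - half, xmax = s$PC1[i] + half,
        ymin = s$PC2[i] - half, ymax = s$PC2[i] + half)
    }
  }
  p
}
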