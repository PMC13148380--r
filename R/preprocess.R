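# Image preprocessing: grayscale conversion, background normalization,
# ROI tiling, blur-based tile filtering and 3x3 aggregation.
#
# Conventions (used throughout the package): images are numeric matrices in
# [0, 1]; origin top-left; 0-based (row, col) coordinates for all tile and
# patch bounds; half-open intervals [start, end). Brightfield polarity: high
# values are bright background/veins, low values are stain.

#' Convert a raster to a single-channel grayscale image
#'
#' Single-channel input is returned unchanged apart from scaling; 3-channel
#' (RGB) input is combined with the Rec. 709 luminance weights
#' (0.2126, 0.7152, 0.0722). Integer-coded rasters (values above 1) are
#' rescaled to `[0, 1]` assuming 8-bit or 16-bit coding.
#'
#' @param raster a numeric matrix (single channel) or a 3D array with three
#'   channels in the third dimension.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
to_grayscale <- function(raster) {
  if (is.matrix(raster)) {
    gray <- raster
  } else if (is.array(raster) && length(dim(raster)) == 3L) {
    nc <- dim(raster)[3L]
    if (nc == 1L) {
      gray <- raster[, , 1L]
    } else if (nc == 3L) {
      w <- c(0.2126, 0.7152, 0.0722)
      gray <- w[1L] * raster[, , 1L] + w[2L] * raster[, , 2L] +
        w[3L] * raster[, , 3L]
    } else {
      stop("raster must have 1 or 3 channels, got ", nc, call. = FALSE)
    }
  } else {
    stop("raster must be a matrix or a 3D array", call. = FALSE)
  }
  if (anyNA(gray)) stop("raster contains NA/NaN values", call. = FALSE)
  mx <- max(gray)
  if (mx > 1) gray <- gray / (if (mx <= 255) 255 else 65535)
  gray
}

#' Read an image file as a grayscale matrix
#'
#' Thin wrapper around [EBImage::readImage()] followed by [to_grayscale()].
#' EBImage stores images column-major with x along the first dimension; the
#' result is transposed so that matrix rows correspond to image rows.
#'
#' @param path path to a TIFF or PNG file.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3L) {
    a <- aperm(a, c(2L, 1L, 3L))
  } else {
    a <- t(a)
  }
  to_grayscale(a)
}

#' Define a background patch
#'
#' A `size_h` x `size_w` window of presumed empty background used for
#' intensity normalization, addressed by its 0-based top-left corner.
#'
#' @param top,left 0-based pixel indices of the patch corner.
#' @param size_h,size_w patch height and width in pixels (default 200).
#' @return An object of class `background_patch`.
#' @export
background_patch <- function(top, left, size_h = 200L, size_w = 200L) {
  stopifnot(top >= 0, left >= 0, size_h >= 1, size_w >= 1)
  structure(list(top = as.integer(top), left = as.integer(left),
                 height = as.integer(size_h), width = as.integer(size_w)),
            class = "background_patch")
}

patch_pixels <- function(image, patch) {
  if (patch$top + patch$height > nrow(image) ||
      patch$left + patch$width > ncol(image))
    stop("background patch extends outside the image", call. = FALSE)
  image[(patch$top + 1L):(patch$top + patch$height),
        (patch$left + 1L):(patch$left + patch$width)]
}

#' Automatically select a background patch
#'
#' Scans `size` x `size` windows on a stride of `size / 2` and returns the
#' window with minimal intensity variance among windows whose mean intensity
#' lies in the top quartile of window means (bright and flat = empty
#' background in brightfield). Ties are broken by scan order (row-major from
#' the top-left). A user-supplied `patch` overrides the scan and is returned
#' unchanged.
#'
#' @param image grayscale matrix.
#' @param size patch side in pixels (default 200).
#' @param patch optional [background_patch()] that short-circuits selection.
#' @return A [background_patch()].
#' @export
select_background_patch <- function(image, size = 200L, patch = NULL) {
  if (!is.null(patch)) {
    stopifnot(inherits(patch, "background_patch"))
    return(patch)
  }
  check_image(image)
  size <- as.integer(size)
  if (nrow(image) < size || ncol(image) < size)
    stop("image is smaller than the requested patch size", call. = FALSE)
  stride <- max(1L, size %/% 2L)
  tops <- unique(c(seq(0L, nrow(image) - size, by = stride),
                   nrow(image) - size))
  lefts <- unique(c(seq(0L, ncol(image) - size, by = stride),
                    ncol(image) - size))
  # row-major scan order: top varies slowest
  grid <- expand.grid(left = lefts, top = tops,
                      KEEP.OUT.ATTRS = FALSE)[, c("top", "left")]
  mu <- va <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    px <- image[(grid$top[i] + 1L):(grid$top[i] + size),
                (grid$left[i] + 1L):(grid$left[i] + size)]
    mu[i] <- mean(px)
    va[i] <- var(as.vector(px))
  }
  bright <- mu >= quantile(mu, 0.75, type = 7)
  idx <- which(bright)[which.min(va[bright])]
  background_patch(grid$top[idx], grid$left[idx], size, size)
}

#' Normalize image intensity by its background level
#'
#' Divides every pixel by the mean intensity of the background patch, so the
#' patch mean of the output is exactly 1. This removes slide-to-slide
#' illumination differences before tiling and texture analysis.
#'
#' @param image grayscale matrix.
#' @param patch a [background_patch()]; defaults to automatic selection via
#'   [select_background_patch()].
#' @return The normalized image (numeric matrix, patch mean exactly 1).
#' @export
normalize_background <- function(image, patch = NULL) {
  check_image(image)
  patch <- select_background_patch(image, patch = patch)
  m <- mean(patch_pixels(image, patch))
  if (m < 1e-6)
    stop(sprintf(
      "background patch at (top=%d, left=%d) has near-zero mean (%g); %s",
      patch$top, patch$left, m, "choose a brighter patch"), call. = FALSE)
  out <- image / m
  attr(out, "background_patch") <- patch
  attr(out, "background_mean") <- m
  out
}

#' Tile a 1500x1500 region of interest into an 8x8 grid
#'
#' Cut positions are `i * 1500 / 8` for `i = 0..8`, rounded half away from
#' zero, i.e. `c(0, 188, 375, 563, 750, 938, 1125, 1313, 1500)`. The
#' resulting 64 tiles alternate between 187 and 188 px per side and exactly
#' partition the ROI (half-open bounds). All tiles start with `keep = TRUE`.
#'
#' @param image grayscale matrix the ROI must fit inside.
#' @param roi_top,roi_left 0-based pixel indices of the ROI corner.
#' @param roi_size ROI side in pixels (default 1500).
#' @param grid number of tiles per side (default 8).
#' @return An object of class `tile_set`: list with `roi`, `row_cuts`,
#'   `col_cuts` and a data frame `tiles` holding 0-based half-open pixel
#'   bounds (`row0`, `row1`, `col0`, `col1`), `keep` flags and `drop_reason`.
#' @export
tile_roi <- function(image, roi_top = 0L, roi_left = 0L, roi_size = 1500L,
                     grid = 8L) {
  check_image(image)
  roi_top <- as.integer(roi_top); roi_left <- as.integer(roi_left)
  roi_size <- as.integer(roi_size); grid <- as.integer(grid)
  if (roi_top < 0 || roi_left < 0 ||
      roi_top + roi_size > nrow(image) || roi_left + roi_size > ncol(image))
    stop("ROI out of image bounds", call. = FALSE)
  cuts <- as.integer(round_half_up((0:grid) * roi_size / grid))
  tiles <- expand.grid(col_idx = seq_len(grid) - 1L,
                       row_idx = seq_len(grid) - 1L,
                       KEEP.OUT.ATTRS = FALSE)[, c("row_idx", "col_idx")]
  tiles$row0 <- roi_top + cuts[tiles$row_idx + 1L]
  tiles$row1 <- roi_top + cuts[tiles$row_idx + 2L]
  tiles$col0 <- roi_left + cuts[tiles$col_idx + 1L]
  tiles$col1 <- roi_left + cuts[tiles$col_idx + 2L]
  tiles$keep <- TRUE
  tiles$drop_reason <- NA_character_
  structure(list(roi = c(top = roi_top, left = roi_left, size = roi_size),
                 grid = grid,
                 row_cuts = roi_top + cuts, col_cuts = roi_left + cuts,
                 tiles = tiles),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("tile_set: %dx%d grid over %dx%d ROI at (top=%d, left=%d)\n",
              x$grid, x$grid, x$roi["size"], x$roi["size"],
              x$roi["top"], x$roi["left"]))
  cat(sprintf("  kept %d / %d tiles\n", sum(x$tiles$keep), nrow(x$tiles)))
  invisible(x)
}

# Extract the pixels of one tile (1-based matrix indexing from 0-based
# half-open bounds).
tile_pixels <- function(image, tile_row) {
  image[(tile_row$row0 + 1L):tile_row$row1,
        (tile_row$col0 + 1L):tile_row$col1, drop = FALSE]
}

#' Flag empty or veinous tiles using a blurred brightness rule
#'
#' Gaussian-blurs the ROI (sigma `blur_sigma`), computes the
#' `top_quantile` (default 90th) percentile of all blurred ROI pixels, and
#' drops a tile (with `drop_reason = "empty_or_vein"`) if the fraction of its
#' blurred pixels strictly above that cutoff exceeds `frac_threshold`
#' (default 10%). On a constant ROI no pixel is strictly above the cutoff, so
#' all tiles are kept.
#'
#' @param tiles a [tile_roi()] result.
#' @param image the (normalized) grayscale matrix the tiles refer to.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param frac_threshold fraction of above-cutoff pixels beyond which a tile
#'   is dropped.
#' @param top_quantile quantile of blurred ROI pixel values used as the
#'   brightness cutoff.
#' @param invert set `TRUE` for fluorescence-style images where stain is
#'   bright; the brightness rule is applied to `1 - image`.
#' @return The `tile_set` with updated `keep` flags and `drop_reason`.
#' @export
filter_tiles <- function(tiles, image, blur_sigma = 2.0,
                         frac_threshold = 0.10, top_quantile = 0.90,
                         invert = FALSE) {
  stopifnot(inherits(tiles, "tile_set"))
  check_image(image)
  roi <- image[(tiles$roi["top"] + 1L):(tiles$roi["top"] + tiles$roi["size"]),
               (tiles$roi["left"] + 1L):(tiles$roi["left"] + tiles$roi["size"])]
  if (invert) roi <- max(roi) - roi
  blurred <- gaussian_blur(roi, sigma = blur_sigma)
  cutoff <- quantile(as.vector(blurred), top_quantile, type = 7, names = FALSE)
  t0 <- tiles$roi["top"]; l0 <- tiles$roi["left"]
  frac <- numeric(nrow(tiles$tiles))
  for (i in seq_len(nrow(tiles$tiles))) {
    tr <- tiles$tiles[i, ]
    bx <- blurred[(tr$row0 - t0 + 1L):(tr$row1 - t0),
                  (tr$col0 - l0 + 1L):(tr$col1 - l0)]
    frac[i] <- mean(bx > cutoff)
  }
  drop <- frac > frac_threshold
  tiles$tiles$keep <- !drop
  tiles$tiles$drop_reason <- ifelse(drop, "empty_or_vein", NA_character_)
  tiles$tiles$bright_fraction <- frac
  attr(tiles, "bright_cutoff") <- cutoff
  tiles
}

#' Gaussian blur by separable spatial convolution
#'
#' Direct separable convolution with a truncated Gaussian kernel (radius
#' `3 * sigma`) and replicate boundary handling. Spatial convolution is used
#' rather than an FFT so that constant regions stay bitwise constant: the
#' tile filter compares blurred values strictly against a percentile cutoff,
#' and FFT round-off ripple (~1e-16) far from edges would otherwise leak
#' through a strict inequality.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return The blurred matrix, same dimensions.
#' @export
gaussian_blur <- function(image, sigma = 2.0) {
  stopifnot(is.matrix(image), sigma > 0)
  rad <- as.integer(ceiling(3 * sigma))
  k <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  k <- k / sum(k)
  n_r <- nrow(image); n_c <- ncol(image)
  out <- matrix(0, n_r, n_c)
  for (o in -rad:rad) {   # along rows (vertical)
    idx <- pmin(pmax(seq_len(n_r) + o, 1L), n_r)
    out <- out + k[o + rad + 1L] * image[idx, , drop = FALSE]
  }
  out2 <- matrix(0, n_r, n_c)
  for (o in -rad:rad) {   # along columns (horizontal)
    idx <- pmin(pmax(seq_len(n_c) + o, 1L), n_c)
    out2 <- out2 + k[o + rad + 1L] * out[, idx, drop = FALSE]
  }
  out2
}

#' Aggregate a tile by block averaging
#'
#' Output cell `(i, j)` is the mean of the input block rows
#' `[b*i, b*i + b)` x cols `[b*j, b*j + b)`. Partial blocks at the bottom or
#' right edge (tile sides not divisible by `block`) use the mean of the
#' available pixels. Output dimensions are `ceiling(dim / block)`.
#'
#' @param pixels numeric matrix (one tile).
#' @param block block side in pixels (default 3).
#' @return The block-averaged matrix.
#' @export
aggregate_tile <- function(pixels, block = 3L) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L, ncol(pixels) >= 1L,
            block >= 1L)
  gi <- (seq_len(nrow(pixels)) - 1L) %/% block
  gj <- (seq_len(ncol(pixels)) - 1L) %/% block
  sums <- rowsum(pixels, gi, reorder = TRUE)
  sums <- t(rowsum(t(sums), gj, reorder = TRUE))
  cnt <- tabulate(gi + 1L) %o% tabulate(gj + 1L)
  out <- sums / cnt
  dimnames(out) <- NULL
  out
}

#' Write a tile set to JSON
#'
#' Serializes the ROI, cut positions, keep flags and drop reasons so a
#' filtered tiling can be archived or inspected outside R.
#'
#' @param tiles a `tile_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tileset_json <- function(tiles, path) {
  stopifnot(inherits(tiles, "tile_set"))
  jsonlite::write_json(
    list(roi = as.list(tiles$roi), grid = tiles$grid,
         row_cuts = tiles$row_cuts, col_cuts = tiles$col_cuts,
         tiles = tiles$tiles),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
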