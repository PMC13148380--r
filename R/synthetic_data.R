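# Synthetic data generators: histology images, per-cell intensity tables and
# expression matrices with planted ground truth. Every downstream stage of the
# package can be exercised against these without any external data; ground
# truth is always returned alongside the data and is only meant for tests and
# validation, never as an input to analysis functions.

#' Configuration for the synthetic histology generator
#'
#' Describes a square brightfield field of view containing dark stained cells
#' on a bright background, optionally aggregated into clusters (a Thomas
#' parent--offspring process) and optionally containing bright circular veins
#' that are kept free of cells. Defaults emulate an F4/80-stained liver
#' section at roughly 0.5 um/px: a 1500 px field, 6 px cell radius, and a
#' macrophage density high enough that tissue regions are visibly textured.
#'
#' @param image_size side of the square image in pixels.
#' @param cell_count number of cells to place.
#' @param cell_radius_px cell radius in pixels.
#' @param clustering_mode `"dispersed"` (uniform centers) or `"clustered"`
#'   (Thomas process: `cluster_count` uniform parents, Gaussian offspring with
#'   standard deviation `cluster_sd_px`).
#' @param cluster_count number of cluster parents (clustered mode).
#' @param cluster_sd_px offspring standard deviation in pixels.
#' @param stain_intensity darkness of a fully stained cell relative to the
#'   background, in `(0, 1]`.
#' @param background_level brightness of empty background and vein interiors,
#'   in `(0, 1]`.
#' @param vein_count number of bright circular veins.
#' @param vein_radius_px vein radius in pixels.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param stratum_probs length-4 probabilities of the negative/low/moderate/
#'   high staining strata assigned to cells.
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the seed and configuration.
#'
#' @return An object of class `histology_sim_config`.
#' @export
histology_sim_config <- function(image_size = 1500L,
                                 cell_count = 2000L,
                                 cell_radius_px = 6,
                                 clustering_mode = c("dispersed", "clustered"),
                                 cluster_count = 6L,
                                 cluster_sd_px = 40,
                                 stain_intensity = 0.6,
                                 background_level = 0.9,
                                 vein_count = 0L,
                                 vein_radius_px = 150,
                                 noise_sd = 0.02,
                                 stratum_probs = c(0.25, 0.25, 0.25, 0.25),
                                 seed = 1L) {
  clustering_mode <- match.arg(clustering_mode)
  stopifnot(image_size > 0, cell_radius_px > 0,
            stain_intensity > 0, stain_intensity <= 1,
            background_level > 0, background_level <= 1,
            noise_sd >= 0, cell_count >= 0, vein_count >= 0,
            length(stratum_probs) == 4L, all(stratum_probs >= 0))
  if (cell_radius_px >= image_size / 2)
    stop("cell_radius_px must be smaller than image_size/2", call. = FALSE)
  if (clustering_mode == "clustered" && cluster_count < 1L)
    stop("clustered mode requires cluster_count >= 1", call. = FALSE)
  if (cell_count * pi * cell_radius_px^2 > image_size^2)
    stop("cells cannot fit: cell_count * pi * r^2 exceeds image area; ",
         "reduce cell_count or cell_radius_px", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 cell_count = as.integer(cell_count),
                 cell_radius_px = cell_radius_px,
                 clustering_mode = clustering_mode,
                 cluster_count = as.integer(cluster_count),
                 cluster_sd_px = cluster_sd_px,
                 stain_intensity = stain_intensity,
                 background_level = background_level,
                 vein_count = as.integer(vein_count),
                 vein_radius_px = vein_radius_px,
                 noise_sd = noise_sd,
                 stratum_probs = stratum_probs / sum(stratum_probs),
                 seed = as.integer(seed)),
            class = "histology_sim_config")
}

# Relative darkness of the four staining strata (fraction of stain_intensity).
.stratum_levels <- c("neg", "low", "moderate", "high")
.stratum_darkness <- c(neg = 0.15, low = 0.45, moderate = 0.75, high = 1)

#' Simulate a brightfield histology image with known ground truth
#'
#' Renders anti-aliased dark disks (cells) on a bright background, with
#' optional clustered placement (Thomas process) and bright cell-free vein
#' disks, then adds Gaussian noise and clips to `[0, 1]`. Cells are assigned
#' one of four staining strata (negative/low/moderate/high) whose darkness
#' scales with `stain_intensity`; the returned cell table records the true
#' center, stratum and intensity of every cell so downstream scoring can be
#' validated against ground truth.
#'
#' @param config a [histology_sim_config()].
#' @return A list with elements
#'   \describe{
#'     \item{image}{`image_size` x `image_size` numeric matrix in `[0, 1]`.}
#'     \item{cells}{data frame with `cell_id`, `x`, `y` (0-based pixel
#'       coordinates), `stratum`, `intensity` (optical-density-like darkness)
#'       and, in clustered mode, the parent cluster id.}
#'     \item{veins}{data frame of vein centers and radii (possibly empty).}
#'     \item{vein_mask}{logical matrix marking vein interiors, or `NULL` when
#'       `vein_count == 0`.}
#'     \item{clip_fraction}{fraction of pixels clipped to `[0, 1]` after
#'       noise.}
#'   }
#' @export
simulate_histology <- function(config) {
  stopifnot(inherits(config, "histology_sim_config"))
  n <- config$image_size
  with_seed(config$seed, {
    veins <- if (config$vein_count > 0L) {
      data.frame(vein_id = seq_len(config$vein_count),
                 x = runif(config$vein_count, 0, n),
                 y = runif(config$vein_count, 0, n),
                 radius = config$vein_radius_px)
    } else {
      data.frame(vein_id = integer(), x = numeric(), y = numeric(),
                 radius = numeric())
    }

    centers <- draw_cell_centers(config, veins)
    ncell <- nrow(centers)
    stratum <- if (ncell > 0L) {
      sample(.stratum_levels, ncell, replace = TRUE,
             prob = config$stratum_probs)
    } else character()
    darkness <- config$stain_intensity * unname(.stratum_darkness[stratum])

    # stamp anti-aliased dark disks in place (single allocation)
    img <- matrix(config$background_level, n, n)
    r <- config$cell_radius_px
    ext <- ceiling(r) + 2L
    for (i in seq_len(ncell)) {
      x <- centers$x[i]; y <- centers$y[i]
      rows <- max(1L, floor(y) - ext):min(n, ceiling(y) + ext)
      cols <- max(1L, floor(x) - ext):min(n, ceiling(x) + ext)
      d <- sqrt(outer(((rows - 1) - y)^2, ((cols - 1) - x)^2, `+`))
      cov <- pmin(pmax(r + 0.5 - d, 0), 1)
      img[rows, cols] <- img[rows, cols] - cov * darkness[i]
    }
    # vein interiors are bright and empty: reset to background
    if (nrow(veins) > 0L) {
      mask <- disk_mask(n, veins)
      img[mask] <- config$background_level
    } else {
      mask <- NULL
    }
    if (config$noise_sd > 0) img <- img + rnorm(n * n, sd = config$noise_sd)
    clipped <- img < 0 | img > 1
    img[img < 0] <- 0; img[img > 1] <- 1
    clip_fraction <- mean(clipped)
    if (clip_fraction > 0)
      message(sprintf("simulate_histology: clipped %.3f%% of pixels to [0,1]",
                      100 * clip_fraction))

    cells <- data.frame(cell_id = seq_len(ncell),
                        x = centers$x, y = centers$y,
                        stratum = factor(stratum, levels = .stratum_levels),
                        intensity = darkness)
    if (!is.null(centers$cluster)) cells$cluster <- centers$cluster

    list(image = img, cells = cells, veins = veins, vein_mask = mask,
         clip_fraction = clip_fraction)
  })
}

# Draw cell centers (continuous 0-based coordinates), dispersed or Thomas
# clustered, rejecting positions inside veins or within a radius of the edge.
draw_cell_centers <- function(config, veins) {
  n <- config$image_size; r <- config$cell_radius_px
  k <- config$cell_count
  if (k == 0L)
    return(data.frame(x = numeric(), y = numeric()))
  ok <- function(x, y) {
    inside <- x >= r & x <= n - r & y >= r & y <= n - r
    if (nrow(veins) > 0L) {
      for (v in seq_len(nrow(veins))) {
        inside <- inside &
          ((x - veins$x[v])^2 + (y - veins$y[v])^2 >
             (veins$radius[v] + r)^2)
      }
    }
    inside
  }
  if (config$clustering_mode == "dispersed") {
    xs <- ys <- numeric(0)
    while (length(xs) < k) {
      m <- 2L * (k - length(xs)) + 16L
      x <- runif(m, 0, n); y <- runif(m, 0, n)
      keep <- ok(x, y)
      xs <- c(xs, x[keep]); ys <- c(ys, y[keep])
    }
    data.frame(x = xs[1:k], y = ys[1:k])
  } else {
    px <- runif(config$cluster_count, r, n - r)
    py <- runif(config$cluster_count, r, n - r)
    xs <- ys <- numeric(0); cl <- integer(0)
    while (length(xs) < k) {
      m <- 2L * (k - length(xs)) + 16L
      pid <- sample.int(config$cluster_count, m, replace = TRUE)
      x <- px[pid] + rnorm(m, sd = config$cluster_sd_px)
      y <- py[pid] + rnorm(m, sd = config$cluster_sd_px)
      keep <- ok(x, y)
      xs <- c(xs, x[keep]); ys <- c(ys, y[keep]); cl <- c(cl, pid[keep])
    }
    data.frame(x = xs[1:k], y = ys[1:k], cluster = cl[1:k])
  }
}

# Logical mask of vein interiors on an n x n grid of 0-based pixel centers.
disk_mask <- function(n, veins) {
  mask <- matrix(FALSE, n, n)
  yy <- 0:(n - 1)
  for (v in seq_len(nrow(veins))) {
    d2 <- outer((yy - veins$y[v])^2, (yy - veins$x[v])^2, `+`)
    mask <- mask | (d2 <= veins$radius[v]^2)
  }
  mask
}

#' Simulate a per-cell staining-intensity table with known strata
#'
#' Draws cells from four intensity strata (negative/low/moderate/high) with
#' Gaussian spread around each stratum mean. The true stratum label is
#' recorded per cell, so threshold-based stratification can be checked
#' against ground truth.
#'
#' @param n_per_stratum integer vector of length 4: number of cells in the
#'   negative, low, moderate and high strata.
#' @param stratum_means increasing numeric vector of length 4 of mean
#'   intensities (optical-density-like, nonnegative).
#' @param sd Gaussian standard deviation around each stratum mean (truncated
#'   at zero).
#' @param seed integer RNG seed.
#' @param region_size side of the square region over which cell positions are
#'   drawn uniformly.
#' @param region_id region label stored on every row.
#' @return A cell table (data frame) with `cell_id`, `x`, `y`, `intensity`,
#'   `true_stratum` and `region_id`.
#' @export
simulate_cell_intensities <- function(n_per_stratum, stratum_means,
                                      sd = 0.02, seed = 1L,
                                      region_size = 1000,
                                      region_id = "region_1") {
  stopifnot(length(n_per_stratum) == 4L, length(stratum_means) == 4L,
            sd >= 0)
  if (any(n_per_stratum < 0))
    stop("n_per_stratum must be nonnegative", call. = FALSE)
  if (is.unsorted(stratum_means, strictly = TRUE))
    stop("stratum_means must be strictly increasing", call. = FALSE)
  n <- sum(n_per_stratum)
  with_seed(seed, {
    stratum <- rep(.stratum_levels, times = n_per_stratum)
    mu <- rep(stratum_means, times = n_per_stratum)
    intensity <- pmax(0, mu + if (sd > 0) rnorm(n, sd = sd) else 0)
    data.frame(cell_id = seq_len(n),
               x = runif(n, 0, region_size),
               y = runif(n, 0, region_size),
               intensity = intensity,
               true_stratum = factor(stratum, levels = .stratum_levels),
               region_id = region_id)
  })
}

#' Configuration for the synthetic expression generator
#'
#' Describes a log2-scale genes x samples matrix over a 2x2 factorial design
#' (genotype: NTC vs sgBap1; treatment: Veh vs CCl4), with a planted up/down
#' activity signature and a block of genotype-by-treatment interaction genes
#' following four per-group pattern templates.
#'
#' The default templates mirror the four qualitative interaction patterns of
#' an acute-damage study: (1) damage-induced genes blunted by knockout,
#' (2) immune genes pre-activated by knockout, (3) regulators high only in
#' untreated control, (4) metabolic genes high only in untreated knockout.
#'
#' @param n_genes total number of genes.
#' @param n_samples_per_group samples per experimental group (4 groups).
#' @param n_signature_up,n_signature_down sizes of the planted up/down
#'   signature gene sets.
#' @param signature_effect log2 shift separating high-activity (NTC) from
#'   low-activity (sgBap1) groups on signature genes.
#' @param n_interaction_genes number of genes following interaction
#'   templates.
#' @param interaction_patterns list of four numeric length-4 vectors giving
#'   per-group mean shifts (group order `NTC_Veh`, `sgBap1_Veh`, `NTC_CCl4`,
#'   `sgBap1_CCl4`).
#' @param noise_sd Gaussian noise standard deviation on the log2 scale.
#' @param seed integer RNG seed.
#' @return An object of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_genes = 2000L,
                                  n_samples_per_group = 3L,
                                  n_signature_up = 150L,
                                  n_signature_down = 150L,
                                  signature_effect = 2,
                                  n_interaction_genes = 400L,
                                  interaction_patterns = list(
                                    c(0, -2, 2, 2),
                                    c(0, 1.5, 3, 3),
                                    c(2, 0, 0, 0),
                                    c(0, 2, 0, 0)),
                                  noise_sd = 0.5,
                                  seed = 1L) {
  stopifnot(n_genes > 0, n_samples_per_group > 0, noise_sd >= 0,
            n_signature_up >= 0, n_signature_down >= 0,
            n_interaction_genes >= 0)
  if (length(interaction_patterns) != 4L)
    stop("interaction_patterns must be a list of 4 templates", call. = FALSE)
  if (any(vapply(interaction_patterns, length, 1L) != 4L))
    stop("each interaction pattern template must have length 4 ",
         "(one mean per experimental group)", call. = FALSE)
  if (n_signature_up + n_signature_down + n_interaction_genes > n_genes)
    stop("signature and interaction gene counts exceed n_genes",
         call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 n_samples_per_group = as.integer(n_samples_per_group),
                 groups = c("NTC_Veh", "sgBap1_Veh", "NTC_CCl4",
                            "sgBap1_CCl4"),
                 n_signature_up = as.integer(n_signature_up),
                 n_signature_down = as.integer(n_signature_down),
                 signature_effect = signature_effect,
                 n_interaction_genes = as.integer(n_interaction_genes),
                 interaction_patterns = interaction_patterns,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate a log2 expression matrix with planted signature and interaction
#' structure
#'
#' Generates a genes x samples matrix on the log2 scale over the 2x2
#' genotype-by-treatment design. Signature-up genes are shifted up by
#' `signature_effect` in the high-activity (NTC) groups and signature-down
#' genes up in the low-activity (sgBap1) groups, so the signed-sum activity
#' score separates genotypes by construction. Interaction genes follow their
#' assigned per-group template. All other genes have a constant baseline plus
#' noise.
#'
#' @param config an [expression_sim_config()].
#' @return A list with `expr` (matrix, genes x samples), `samples` (data
#'   frame: sample, genotype, treatment, group) and `truth` (data frame:
#'   gene, role in `background`/`signature_up`/`signature_down`/
#'   `interaction`, and `pattern` id for interaction genes).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "expression_sim_config"))
  g <- config$n_genes
  npg <- config$n_samples_per_group
  groups <- rep(config$groups, each = npg)
  ns <- length(groups)
  genes <- sprintf("gene_%04d", seq_len(g))
  samples <- data.frame(
    sample = paste0(rep(config$groups, each = npg), "_", seq_len(npg)),
    genotype = ifelse(grepl("^sgBap1", groups), "sgBap1", "NTC"),
    treatment = ifelse(grepl("CCl4$", groups), "CCl4", "Veh"),
    group = factor(groups, levels = config$groups))

  role <- rep("background", g)
  pattern <- rep(NA_integer_, g)
  iu <- seq_len(config$n_signature_up)
  id <- seq_len(config$n_signature_down) + config$n_signature_up
  ii <- seq_len(config$n_interaction_genes) +
    config$n_signature_up + config$n_signature_down
  role[iu] <- "signature_up"; role[id] <- "signature_down"
  role[ii] <- "interaction"

  with_seed(config$seed, {
    baseline <- rnorm(g, mean = 8, sd = 1.5)
    expr <- matrix(rep(baseline, ns), nrow = g, ncol = ns)
    high_activity <- samples$genotype == "NTC"
    expr[iu, high_activity] <- expr[iu, high_activity] +
      config$signature_effect
    expr[id, !high_activity] <- expr[id, !high_activity] +
      config$signature_effect
    if (length(ii) > 0L) {
      pattern[ii] <- rep_len(seq_len(4L), length(ii))
      gidx <- as.integer(samples$group)
      for (p in 1:4) {
        rows <- ii[pattern[ii] == p]
        shift <- config$interaction_patterns[[p]][gidx]
        expr[rows, ] <- expr[rows, ] + rep(shift, each = length(rows))
      }
    }
    if (config$noise_sd > 0)
      expr <- expr + matrix(rnorm(g * ns, sd = config$noise_sd), g, ns)
    dimnames(expr) <- list(genes, samples$sample)
    list(expr = expr, samples = samples,
         truth = data.frame(gene = genes, role = role, pattern = pattern))
  })
}
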