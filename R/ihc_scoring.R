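# IHC scoring from per-cell intensity tables: intensity stratification,
# percent-positive and H-score per region, 500x500 vein-patch restriction,
# and one-way ANOVA comparison across experimental groups.

#' Intensity cutoffs for IHC stratification
#'
#' Three increasing thresholds split per-cell staining intensity into
#' negative / low / moderate / high strata. Presets match common DAB marker
#' settings: `"f480"` uses low = 0.05, medium = 0.4, high = 0.6; `"cd3"`
#' uses low = 0.2, medium = 0.4, high = 0.6.
#'
#' @param low,medium,high increasing positive thresholds.
#' @param marker marker name (bookkeeping only).
#' @return An object of class `intensity_cutoffs`.
#' @export
intensity_cutoffs <- function(low, medium, high, marker = "custom") {
  stopifnot(is.numeric(low), is.numeric(medium), is.numeric(high))
  if (!(0 < low && low < medium && medium < high))
    stop("cutoffs must satisfy 0 < low < medium < high", call. = FALSE)
  structure(list(low = low, medium = medium, high = high, marker = marker),
            class = "intensity_cutoffs")
}

#' @rdname intensity_cutoffs
#' @param preset `"f480"` or `"cd3"`.
#' @export
cutoff_preset <- function(preset = c("f480", "cd3")) {
  preset <- match.arg(preset)
  switch(preset,
         f480 = intensity_cutoffs(0.05, 0.4, 0.6, marker = "F4/80"),
         cd3 = intensity_cutoffs(0.2, 0.4, 0.6, marker = "CD3"))
}

#' Assign staining strata to cells
#'
#' Boundary convention: a cell exactly at a cutoff enters the higher stratum
#' (`neg` if `intensity < low`; `low` if `low <= intensity < medium`;
#' `moderate` if `medium <= intensity < high`; `high` if
#' `intensity >= high`).
#'
#' @param cells data frame with an `intensity` column (nonnegative).
#' @param cutoffs an [intensity_cutoffs()].
#' @return `cells` with an added factor column `stratum`.
#' @export
stratify_cells <- function(cells, cutoffs) {
  stopifnot(is.data.frame(cells), inherits(cutoffs, "intensity_cutoffs"))
  if (nrow(cells) == 0L) {
    cells$stratum <- factor(character(), levels = .stratum_levels)
    return(cells)
  }
  if (!"intensity" %in% names(cells))
    stop("cells must have an 'intensity' column", call. = FALSE)
  if (any(cells$intensity < 0))
    stop("intensities must be nonnegative", call. = FALSE)
  br <- c(-Inf, cutoffs$low, cutoffs$medium, cutoffs$high, Inf)
  cells$stratum <- cut(cells$intensity, breaks = br, right = FALSE,
                       labels = .stratum_levels)
  cells
}

#' H-score and percent positivity per region
#'
#' For each region, computes the percentage of cells in each stratum and the
#' H-score `1 * %low + 2 * %moderate + 3 * %high` (range 0--300), plus
#' percent positive = `100 - %neg`. Regions with zero cells are skipped with
#' a warning rather than zero-filled.
#'
#' @param cells a stratified cell table (see [stratify_cells()]); if a
#'   `stratum` column is absent, `cutoffs` must be supplied.
#' @param by name of the grouping column (default `"region_id"`); if the
#'   column is absent all cells form one region.
#' @param cutoffs optional [intensity_cutoffs()] applied when `stratum` is
#'   missing.
#' @return A data frame of class `hscore_result` with one row per region:
#'   `region_id`, `n_cells`, `pct_neg`, `pct_low`, `pct_moderate`,
#'   `pct_high`, `h_score`, `percent_positive`, plus any constant per-region
#'   annotation columns (`condition`, `sample_id`, `vein_type`) carried over.
#' @export
h_score <- function(cells, by = "region_id", cutoffs = NULL) {
  stopifnot(is.data.frame(cells))
  if (!"stratum" %in% names(cells)) {
    if (is.null(cutoffs))
      stop("cells carry no 'stratum' column; supply cutoffs", call. = FALSE)
    cells <- stratify_cells(cells, cutoffs)
  }
  region <- if (by %in% names(cells)) as.character(cells[[by]])
            else rep("all", nrow(cells))
  ids <- unique(region)
  carry <- intersect(c("condition", "sample_id", "vein_type"), names(cells))
  rows <- lapply(ids, function(id) {
    sub <- cells[region == id, , drop = FALSE]
    n <- nrow(sub)
    if (n == 0L) return(NULL)
    pct <- 100 * as.vector(table(sub$stratum)[.stratum_levels]) / n
    pct[is.na(pct)] <- 0
    out <- data.frame(region_id = id, n_cells = n,
                      pct_neg = pct[1L], pct_low = pct[2L],
                      pct_moderate = pct[3L], pct_high = pct[4L],
                      h_score = pct[2L] + 2 * pct[3L] + 3 * pct[4L],
                      percent_positive = 100 - pct[1L])
    for (cc in carry) {
      u <- unique(as.character(sub[[cc]]))
      out[[cc]] <- if (length(u) == 1L) u else NA_character_
    }
    out
  })
  empty <- ids[vapply(rows, is.null, TRUE)]
  if (length(empty) > 0L)
    warning("skipped empty region(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  class(out) <- c("hscore_result", class(out))
  out
}

#' Define square vein patches
#'
#' @param center_x,center_y patch centers in pixels.
#' @param vein_type `"central"` or `"portal"` per patch.
#' @param size patch side in pixels (default 500).
#' @param patch_id optional identifiers.
#' @return A data frame of patch definitions with half-open bounds
#'   `[x0, x1) x [y0, y1)`.
#' @export
vein_patches <- function(center_x, center_y, vein_type, size = 500,
                         patch_id = NULL) {
  stopifnot(length(center_x) == length(center_y),
            length(vein_type) == length(center_x))
  vein_type <- match.arg(vein_type, c("central", "portal"),
                         several.ok = TRUE)
  if (is.null(patch_id)) patch_id <- paste0("patch_", seq_along(center_x))
  data.frame(patch_id = patch_id,
             x0 = center_x - size / 2, x1 = center_x + size / 2,
             y0 = center_y - size / 2, y1 = center_y + size / 2,
             vein_type = vein_type)
}

#' H-scores restricted to vein patches
#'
#' Filters cells to each square patch by half-open bounds
#' (`x0 <= x < x1`, `y0 <= y < y1`), then scores each patch with
#' [h_score()], labeling results with the patch's vein type. Overlapping
#' patches are allowed (cells count in every patch containing them) but are
#' reported with a message; empty patches are skipped with a warning.
#'
#' @param cells a (stratified) cell table with `x`, `y` columns.
#' @param patches a [vein_patches()] data frame.
#' @param cutoffs optional [intensity_cutoffs()] if `cells` lack `stratum`.
#' @return An `hscore_result` data frame, one row per nonempty patch, with
#'   `vein_type`.
#' @export
vein_patch_scores <- function(cells, patches, cutoffs = NULL) {
  stopifnot(is.data.frame(cells), is.data.frame(patches))
  if (!"stratum" %in% names(cells)) {
    if (is.null(cutoffs))
      stop("cells carry no 'stratum' column; supply cutoffs", call. = FALSE)
    cells <- stratify_cells(cells, cutoffs)
  }
  if (overlapping_patches(patches))
    message("vein_patch_scores: some patches overlap; ",
            "cells in the overlap are counted in each patch")
  pieces <- lapply(seq_len(nrow(patches)), function(i) {
    p <- patches[i, ]
    sub <- cells[cells$x >= p$x0 & cells$x < p$x1 &
                   cells$y >= p$y0 & cells$y < p$y1, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("skipped empty patch: ", p$patch_id, call. = FALSE)
      return(NULL)
    }
    sub$region_id <- p$patch_id
    sub$vein_type <- p$vein_type
    sub
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L)
    stop("no patch contains any cells", call. = FALSE)
  h_score(do.call(rbind, pieces), by = "region_id")
}

overlapping_patches <- function(patches) {
  n <- nrow(patches)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (patches$x0[i] < patches$x1[j] && patches$x1[i] > patches$x0[j] &&
        patches$y0[i] < patches$y1[j] && patches$y1[i] > patches$y0[j])
      return(TRUE)
  }
  FALSE
}

#' One-way ANOVA of H-scores across groups
#'
#' Classical fixed-effects one-way ANOVA of region-level H-scores across
#' experimental groups via [stats::aov()]. Degenerate inputs (zero residual
#' and zero between-group variance, so F is 0/0) are flagged rather than
#' reported as a number.
#'
#' @param scores an [h_score()] result (or any data frame with the score and
#'   grouping columns).
#' @param group name of the grouping column (default `"condition"`).
#' @param value name of the response column (default `"h_score"`).
#' @return A list with `f_statistic`, `df_between`, `df_within`, `p_value`,
#'   `group_means` and logical `degenerate`.
#' @export
compare_groups <- function(scores, group = "condition", value = "h_score") {
  stopifnot(is.data.frame(scores), group %in% names(scores),
            value %in% names(scores))
  g <- factor(scores[[group]])
  y <- scores[[value]]
  if (nlevels(g) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("each group needs at least 2 regions", call. = FALSE)
  if (diff(range(y)) == 0) {
    # zero between- and within-group variance: F is 0/0, undefined
    return(list(f_statistic = NA_real_,
                df_between = nlevels(g) - 1L,
                df_within = length(y) - nlevels(g),
                p_value = NA_real_,
                group_means = tapply(y, g, mean),
                degenerate = TRUE))
  }
  fit <- aov(y ~ g)
  tab <- summary(fit)[[1L]]
  fstat <- tab[["F value"]][1L]
  pval <- tab[["Pr(>F)"]][1L]
  if (!is.finite(fstat)) { fstat <- Inf; pval <- 0 }  # perfect separation
  list(f_statistic = fstat,
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       p_value = pval,
       group_means = tapply(y, g, mean),
       degenerate = FALSE)
}
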