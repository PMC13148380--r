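# Interaction-gene pattern analysis: per-gene median centering,
# 1 - Pearson correlation distance with average-linkage (UPGMA) hierarchical
# clustering, a fixed k-cluster cut, and per-cluster per-group expression
# summaries.

#' Median-center an expression matrix across samples
#'
#' Subtracts each gene row's across-sample median, so every row median is 0.
#' Centering is idempotent.
#'
#' @param expr numeric matrix, genes x samples (at least 2 samples).
#' @return The centered matrix with the original medians in attribute
#'   `"medians"`.
#' @export
median_center <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr), ncol(expr) >= 2L)
  med <- apply(expr, 1L, median)
  out <- expr - med
  attr(out, "medians") <- med
  out
}

#' Cluster gene expression profiles by correlation distance
#'
#' Pairwise distance `d(g, h) = 1 - Pearson(g, h)` between gene rows,
#' agglomerative average linkage (UPGMA) via [stats::hclust()], and a flat
#' cut into `k` clusters (the standard [stats::cutree()] cut, i.e. cutting
#' the `k - 1` highest merges). Zero-variance rows, for which Pearson
#' correlation is undefined, are removed first and reported. Cluster labels
#' are relabeled 1..k by decreasing cluster size, ties broken by the
#' lexicographically smallest gene identifier in the cluster.
#'
#' @param centered numeric matrix, genes x samples (typically
#'   [median_center()] output).
#' @param k number of clusters (default 4).
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector gene -> label), `hclust` (the dendrogram),
#'   `k`, and `removed` (zero-variance genes).
#' @export
cluster_genes <- function(centered, k = 4L) {
  stopifnot(is.matrix(centered), is.numeric(centered))
  if (is.null(rownames(centered)))
    rownames(centered) <- paste0("gene_", seq_len(nrow(centered)))
  v <- apply(centered, 1L, var)
  removed <- rownames(centered)[v == 0]
  if (length(removed) > 0L)
    message("cluster_genes: removed ", length(removed),
            " zero-variance gene(s) (Pearson undefined)")
  m <- centered[v > 0, , drop = FALSE]
  if (nrow(m) < k)
    stop("fewer genes (", nrow(m), ") than clusters (", k, ")",
         call. = FALSE)
  d <- as.dist(1 - cor(t(m)))
  hc <- hclust(d, method = "average")
  raw <- cutree(hc, k = k)
  # relabel by decreasing size; ties by smallest member gene id
  sizes <- table(raw)
  first_gene <- vapply(names(sizes), function(lbl)
    min(names(raw)[raw == as.integer(lbl)]), "")
  ord <- order(-as.integer(sizes), first_gene)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(sizes)
  cluster <- setNames(relabel[raw], names(raw))
  structure(list(cluster = cluster, hclust = hc, k = as.integer(k),
                 removed = removed),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d genes in %d clusters (sizes: %s)\n",
              length(x$cluster), x$k,
              paste(table(x$cluster), collapse = ", ")))
  invisible(x)
}

#' Per-cluster per-group expression summaries
#'
#' For each cluster and experimental group, pools the centered expression of
#' all member genes over all samples of the group and reports the median and
#' quartiles (what a per-cluster boxplot displays).
#'
#' @param centered centered matrix, genes x samples.
#' @param assignment a [cluster_genes()] result.
#' @param groups vector (length = samples) of group labels.
#' @return Data frame with `cluster`, `group`, `n_values`, `q1`, `median`,
#'   `q3`.
#' @export
cluster_profiles <- function(centered, assignment, groups) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            is.matrix(centered), length(groups) == ncol(centered))
  genes <- names(assignment$cluster)
  missing <- setdiff(genes, rownames(centered))
  if (length(missing) > 0L)
    stop("assignment covers genes absent from the matrix", call. = FALSE)
  groups <- factor(groups, levels = unique(groups))
  out <- list()
  for (cl in sort(unique(assignment$cluster))) {
    sub <- centered[genes[assignment$cluster == cl], , drop = FALSE]
    for (g in levels(groups)) {
      v <- as.vector(sub[, groups == g, drop = FALSE])
      qs <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, group = g, n_values = length(v),
        q1 = qs[1L], median = qs[2L], q3 = qs[3L])
    }
  }
  do.call(rbind, out)
}

#' Export a dendrogram as Newick text
#'
#' @param assignment a [cluster_genes()] result.
#' @return A single Newick string (requires the \pkg{ape} package).
#' @export
dendrogram_newick <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!requireNamespace("ape", quietly = TRUE))
    stop("the 'ape' package is required for Newick export", call. = FALSE)
  ape::write.tree(ape::as.phylo(assignment$hclust))
}
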