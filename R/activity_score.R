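# Signed-sum gene-signature activity scoring on log2 expression, with
# ortholog mapping of signatures and a reduced-set sensitivity check.

#' Define an up/down signature gene set
#'
#' @param up_genes,down_genes character vectors of gene identifiers; the two
#'   sets must be disjoint and nonempty.
#' @param species species label (bookkeeping).
#' @param provenance free-text origin of the signature.
#' @return An object of class `signature_gene_set`.
#' @export
signature_gene_set <- function(up_genes, down_genes, species = "unknown",
                               provenance = "") {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  if (length(up_genes) == 0L || length(down_genes) == 0L)
    stop("both up and down gene sets must be nonempty", call. = FALSE)
  both <- intersect(up_genes, down_genes)
  if (length(both) > 0L)
    stop("genes in both up and down sets: ",
         paste(head(both, 5L), collapse = ", "), call. = FALSE)
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 species = species, provenance = provenance),
            class = "signature_gene_set")
}

#' Signed-sum activity score per sample
#'
#' For each sample, sums the log2 expression of the signature's up-genes with
#' weight +1 and of its down-genes with weight -1:
#' `score(s) = sum(expr[up, s]) - sum(expr[down, s])`. Lower scores indicate
#' less pathway activity. Signature genes absent from the matrix are skipped
#' and reported in the coverage attribute; raw expression values are used by
#' default (no per-gene centering), with an optional per-gene z-scoring mode.
#'
#' @param expr numeric matrix of log2 normalized expression, genes x samples,
#'   with gene identifiers as row names.
#' @param sig a [signature_gene_set()].
#' @param z_score z-score each signature gene across samples before summing
#'   (default `FALSE`; the raw signed sum is scale-dominated by highly
#'   expressed genes, which is the documented default behavior).
#' @return Named numeric vector of per-sample scores with a `coverage`
#'   attribute listing `n_up_used`, `n_down_used`, `n_missing` and the
#'   coverage fraction.
#' @export
activity_score <- function(expr, sig, z_score = FALSE) {
  stopifnot(is.matrix(expr), is.numeric(expr),
            inherits(sig, "signature_gene_set"))
  if (is.null(rownames(expr)))
    stop("expr must have gene identifiers as row names", call. = FALSE)
  if (anyNA(expr)) stop("expr contains missing values", call. = FALSE)
  up <- intersect(sig$up_genes, rownames(expr))
  dn <- intersect(sig$down_genes, rownames(expr))
  if (length(up) + length(dn) == 0L)
    stop("no signature gene found in the expression matrix; ",
         "matrix genes look like: ",
         paste(head(rownames(expr), 3L), collapse = ", "),
         " vs signature genes: ",
         paste(head(c(sig$up_genes, sig$down_genes), 3L), collapse = ", "),
         call. = FALSE)
  x <- expr
  if (z_score) {
    genes <- c(up, dn)
    sds <- apply(x[genes, , drop = FALSE], 1L, sd)
    sds[sds == 0] <- 1
    x[genes, ] <- (x[genes, , drop = FALSE] -
                     rowMeans(x[genes, , drop = FALSE])) / sds
  }
  score <- colSums(x[up, , drop = FALSE]) - colSums(x[dn, , drop = FALSE])
  n_sig <- length(sig$up_genes) + length(sig$down_genes)
  attr(score, "coverage") <- list(
    n_up_used = length(up), n_down_used = length(dn),
    n_missing = n_sig - length(up) - length(dn),
    fraction = (length(up) + length(dn)) / n_sig)
  score
}

#' Map a signature to another species via an ortholog table
#'
#' Translates each signature gene through a source-to-target ortholog map
#' (many-to-one allowed), collapsing duplicate targets. Genes without an
#' ortholog are excluded and reported with the exclusion fraction; a target
#' gene mapped into both the up and the down set is removed from both and
#' reported.
#'
#' @param sig a [signature_gene_set()].
#' @param ortholog_map data frame with columns `source` and `target`.
#' @param species label for the mapped signature.
#' @return A list with `signature` (the mapped [signature_gene_set()]) and
#'   `report` (excluded genes, exclusion fraction, conflicted targets).
#' @export
map_orthologs <- function(sig, ortholog_map, species = "target") {
  stopifnot(inherits(sig, "signature_gene_set"),
            is.data.frame(ortholog_map),
            all(c("source", "target") %in% names(ortholog_map)))
  map <- ortholog_map[!duplicated(ortholog_map$source), , drop = FALSE]
  lookup <- setNames(as.character(map$target), as.character(map$source))
  translate <- function(genes) {
    hit <- genes[genes %in% names(lookup)]
    list(mapped = unique(unname(lookup[hit])),
         excluded = setdiff(genes, hit))
  }
  up <- translate(sig$up_genes)
  dn <- translate(sig$down_genes)
  conflict <- intersect(up$mapped, dn$mapped)
  up_final <- setdiff(up$mapped, conflict)
  dn_final <- setdiff(dn$mapped, conflict)
  n_total <- length(sig$up_genes) + length(sig$down_genes)
  excluded <- c(up$excluded, dn$excluded)
  list(signature = signature_gene_set(
         up_final, dn_final, species = species,
         provenance = paste0("ortholog-mapped from ", sig$species)),
       report = list(excluded_genes = excluded,
                     n_excluded = length(excluded),
                     exclusion_fraction = length(excluded) / n_total,
                     conflicted_targets = conflict))
}

#' Sensitivity of activity scores to signature reduction
#'
#' Pearson correlation between per-sample activity scores computed from a
#' full and from a reduced signature (e.g. after ortholog exclusion). A
#' zero-variance score vector makes the correlation undefined; this is
#' flagged rather than returned as a number.
#'
#' @param expr expression matrix (genes x samples, at least 3 samples).
#' @param full,reduced [signature_gene_set()]s.
#' @return A list with `r` (Pearson correlation, `NA` when undefined),
#'   `degenerate`, and the two score vectors.
#' @export
sensitivity_check <- function(expr, full, reduced) {
  if (ncol(expr) < 3L)
    stop("need at least 3 samples", call. = FALSE)
  s_full <- activity_score(expr, full)
  s_red <- activity_score(expr, reduced)
  degenerate <- sd(s_full) == 0 || sd(s_red) == 0
  list(r = if (degenerate) NA_real_ else cor(s_full, s_red),
       degenerate = degenerate,
       score_full = s_full, score_reduced = s_red)
}
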