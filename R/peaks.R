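# Peak-set similarity and motif-enrichment rank clustering.

peaks_to_granges <- function(x) {
  GenomicRanges::reduce(GenomicRanges::GRanges(
    x$chrom, IRanges::IRanges(x$start + 1L, x$end)))
}

#' Base-pair Jaccard similarity of two peak sets
#'
#' Intersection over union of covered base pairs between two interval sets
#' (0-based half-open, merged per chromosome before comparison).
#'
#' @param a,b Peak-set tibbles with `chrom`, `start`, `end` columns (e.g.
#'   from [read_bed()] or [simulate_peak_sets()]).
#' @return Similarity in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("Jaccard similarity is undefined for an empty peak set", call. = FALSE)
  }
  ga <- peaks_to_granges(a)
  gb <- peaks_to_granges(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  inter <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
  uni <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::union(ga, gb, ignore.strand = TRUE))))
  inter / uni
}

#' Pairwise Jaccard similarity matrix
#'
#' @param sets Named list of peak-set tibbles (names must be distinct).
#' @return Symmetric numeric matrix with unit diagonal, dimnames from
#'   `names(sets)`.
#' @export
jaccard_matrix <- function(sets) {
  if (length(sets) < 2L) stop("need at least two peak sets", call. = FALSE)
  nms <- names(sets)
  if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))) {
    stop("peak sets must have distinct non-empty names", call. = FALSE)
  }
  m <- length(sets)
  out <- diag(1, m)
  dimnames(out) <- list(nms, nms)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      out[i, j] <- out[j, i] <- jaccard(sets[[i]], sets[[j]])
    }
  }
  out
}

#' Rank motif enrichment p-values within each sample
#'
#' Converts a motif-by-sample matrix of enrichment p-values to within-sample
#' ranks (rank 1 = smallest p, i.e. strongest enrichment; ties receive the
#' average rank). Ranking makes enrichment profiles comparable across
#' studies with different overall binding-specificity scales.
#'
#' @param p_values Numeric matrix (rows = motifs, columns = samples) with
#'   all entries in (0, 1], or a tibble whose first column holds motif names
#'   and remaining columns hold per-sample p-values.
#' @return Numeric matrix of ranks with the same dimnames.
#' @export
rank_enrichments <- function(p_values) {
  if (is.data.frame(p_values)) {
    mat <- as.matrix(p_values[, -1L, drop = FALSE])
    rownames(mat) <- as.character(p_values[[1L]])
    p_values <- mat
  }
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("enrichment p-values must lie in (0, 1] with no missing cells", call. = FALSE)
  }
  apply(p_values, 2L, rank)
}

#' Cluster samples by their motif-enrichment rank profiles
#'
#' Hierarchical clustering (average linkage) of samples using distance
#' 1 - Spearman correlation between rank columns. Samples are ordered by
#' name before clustering so the leaf order is deterministic.
#'
#' @param ranks Rank matrix from [rank_enrichments()] (rows = motifs,
#'   columns = samples, >= 2 samples).
#' @return List of class `motif_clustering` with elements `hclust` (the
#'   [stats::hclust] tree), `leaf_order` (sample names in dendrogram order)
#'   and `distance` (the distance matrix used).
#' @export
cluster_rank_profiles <- function(ranks) {
  if (ncol(ranks) < 2L) stop("need at least two samples to cluster", call. = FALSE)
  if (is.null(colnames(ranks))) colnames(ranks) <- sprintf("sample%d", seq_len(ncol(ranks)))
  ranks <- ranks[, order(colnames(ranks)), drop = FALSE]
  sds <- apply(ranks, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant rank profile (distance undefined): %s",
                 paste(colnames(ranks)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  rho <- stats::cor(ranks, method = "spearman")
  d <- stats::as.dist(1 - rho)
  hc <- stats::hclust(d, method = "average")
  structure(list(
    hclust = hc,
    leaf_order = hc$labels[hc$order],
    distance = as.matrix(d)
  ), class = "motif_clustering")
}

#' Export a motif clustering as a Newick tree
#'
#' @param clustering A [cluster_rank_profiles()] result.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(clustering, path = NULL) {
  tree <- ape::as.phylo(clustering$hclust)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a motif-enrichment p-value table
#'
#' Reads the TSV contract for motif enrichment results: first column motif
#' names, remaining columns one per sample, entries p-values in (0, 1].
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (rows = motifs, columns = samples).
#' @export
read_motif_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- as.character(raw[[1L]])
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("motif table has missing cells", call. = FALSE)
  mat
}
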