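## Cross-modality concordance: cluster-mean z-score profiles, the RNA x ATAC
## Pearson concordance matrix over highly variable genes, and pseudobulk
## bin-profile correlation.

#' Cluster-mean z-score profile matrix
#'
#' Computes per-cluster means of each gene, then z-scores each gene across
#' clusters (sample SD convention, i.e. divide by n_clusters - 1, as `scale()`
#' does; two clusters with means 2 and 4 give -0.707 / +0.707). Constant
#' genes map to all-zero columns.
#'
#' @param m Cells x genes matrix (normalized values or activity scores).
#' @param labels Named character vector, barcode -> cluster, covering all
#'   rows; at least two clusters.
#' @param gene_subset Optional character vector restricting the columns.
#' @param sd_convention `"sample"` (default) or `"population"`.
#' @return Dense matrix, clusters x genes, z-scored per gene.
#' @export
cluster_mean_zscores <- function(m, labels, gene_subset = NULL,
                                 sd_convention = c("sample", "population")) {
  sd_convention <- match.arg(sd_convention)
  if (is.null(names(labels))) names(labels) <- rownames(m)
  labels <- labels[rownames(m)]
  if (anyNA(labels)) stop("every cell must carry a cluster label")
  if (!is.null(gene_subset)) m <- m[, gene_subset, drop = FALSE]
  cl <- sort(unique(unname(labels)))
  if (length(cl) < 2) stop("z-scores need at least two clusters")
  means <- do.call(rbind, lapply(cl, function(g)
    Matrix::colMeans(m[labels == g, , drop = FALSE])))
  rownames(means) <- cl
  mu <- colMeans(means)
  dev <- sweep(means, 2, mu)
  denom <- if (sd_convention == "population") nrow(means) else nrow(means) - 1
  sdv <- sqrt(colSums(dev^2) / denom)
  z <- sweep(dev, 2, ifelse(sdv > 0, sdv, 1), "/")
  z[, sdv == 0] <- 0
  z
}

#' RNA x ATAC cluster concordance matrix
#'
#' All pairwise Pearson correlations between RNA-cluster and ATAC-cluster
#' z-score profiles over a shared highly-variable-gene set (the intersection
#' of `hvg` with both profile matrices' genes).
#'
#' @param rna_profiles,atac_profiles Cluster x gene matrices from
#'   [cluster_mean_zscores()].
#' @param hvg Character vector of genes to correlate over (at least 3 must be
#'   shared).
#' @return Matrix of Pearson correlations, RNA clusters x ATAC clusters, with
#'   attribute `n_genes` (size of the shared set).
#' @export
concordance_matrix <- function(rna_profiles, atac_profiles, hvg) {
  shared <- intersect(intersect(hvg, colnames(rna_profiles)),
                      colnames(atac_profiles))
  if (length(shared) < 3)
    stop("fewer than 3 shared genes between the profile matrices")
  r <- stats::cor(t(rna_profiles[, shared, drop = FALSE]),
                  t(atac_profiles[, shared, drop = FALSE]))
  attr(r, "n_genes") <- length(shared)
  r
}

#' Correlate two pseudobulk bin profiles
#'
#' Rank (Spearman, default; average ranks on ties) or linear (Pearson)
#' correlation over aligned bin count vectors. The two profiles must share an
#' identical bin universe.
#'
#' @param a,b [build_pseudobulk_profile()] results.
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation coefficient.
#' @export
pseudobulk_correlation <- function(a, b, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (!identical(a[, c("chrom", "start", "end")],
                 b[, c("chrom", "start", "end")]))
    stop("pseudobulk profiles have mismatched bin universes")
  stats::cor(a$count, b$count, method = method)
}

#' Write a concordance matrix as TSV
#'
#' @param x Matrix from [concordance_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concordance_table <- function(x, path) {
  df <- data.frame(cluster = rownames(x), as.data.frame(x),
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
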