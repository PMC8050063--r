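## scRNA normalization, highly-variable-gene selection and Wilcoxon
## differential expression with the detection / fold-change prefilters of the
## study design: a gene is differentially expressed for a group if detected
## in at least 25% of one of the two compared groups, has at least 0.25 log
## fold change, and survives Benjamini-Hochberg at 0.05 in a two-sided
## Wilcoxon rank-sum test.

#' RPM-log normalization
#'
#' `x -> log(1 + scale * x / cell_total)`, natural log, reads-per-million
#' scaling by default (the common 1e4-scale variant is available through
#' `scale`).
#'
#' @param counts Raw count matrix, cells x genes; every cell must have total
#'   count > 0.
#' @param scale Library-size scale factor (default `1e6`).
#' @return Dense numeric matrix of normalized values.
#' @export
normalize_rpm_log <- function(counts, scale = 1e6) {
  tot <- Matrix::rowSums(counts)
  if (any(tot <= 0)) {
    bad <- rownames(counts)[which(tot <= 0)]
    stop("cells with zero total count: ", paste(head(bad, 5), collapse = ", "))
  }
  log1p(scale * as.matrix(counts) / tot)
}

## Two-sided rank-sum p-value. Exact enumeration-equivalent distribution when
## both samples are small and tie-free; otherwise the normal approximation
## with continuity and tie correction.
rank_sum_p <- function(x, y, exact_max = 10) {
  exact <- min(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Wilcoxon differential expression for one group
#'
#' Compares the focal group against all other cells, gene by gene. Genes are
#' prefiltered before testing: the larger of the two detection fractions must
#' reach `min_pct` and the absolute log fold change must reach `min_logfc`.
#' Log fold change is computed as
#' `log(mean(expm1(norm)) + 1)` in-group minus out-group (natural log).
#' Remaining genes are tested two-sided; BH adjustment is applied across the
#' tested genes; significance means adjusted p strictly below `alpha`.
#'
#' @param normalized Normalized matrix from [normalize_rpm_log()], cells x
#'   genes.
#' @param groups Named character vector, barcode -> group label, covering all
#'   rows.
#' @param focal Focal group label (must be present).
#' @param min_pct Detection prefilter (default 0.25).
#' @param min_logfc Fold-change prefilter (default 0.25, natural-log scale).
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return data.frame with one row per tested gene: `gene`, `group`,
#'   `logfc`, `pct_in`, `pct_out`, `p`, `p_adj`, `significant`.
#' @export
wilcoxon_de <- function(normalized, groups, focal, min_pct = 0.25,
                        min_logfc = 0.25, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- rownames(normalized)
  groups <- groups[rownames(normalized)]
  if (anyNA(groups)) stop("every cell must carry a group label")
  if (!focal %in% groups) stop("focal label not present: ", focal)
  in_g <- groups == focal
  if (sum(in_g) < 2 || sum(!in_g) < 2)
    stop("need >= 2 cells in both the focal group and the rest")
  xin <- normalized[in_g, , drop = FALSE]
  xout <- normalized[!in_g, , drop = FALSE]
  pct_in <- colMeans(xin > 0)
  pct_out <- colMeans(xout > 0)
  logfc <- log(colMeans(expm1(xin)) + 1) - log(colMeans(expm1(xout)) + 1)
  test <- pmax(pct_in, pct_out) >= min_pct & abs(logfc) >= min_logfc
  test[is.na(test)] <- FALSE   # overflowed fold changes fail the prefilter
  genes <- colnames(normalized)[test]
  p <- vapply(genes, function(g) rank_sum_p(xin[, g], xout[, g]), numeric(1))
  p_adj <- bh_adjust(p)
  data.frame(gene = genes, group = focal, logfc = logfc[test],
             pct_in = pct_in[test], pct_out = pct_out[test],
             p = unname(p), p_adj = unname(p_adj),
             significant = unname(p_adj < alpha),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Wilcoxon differential expression for every group
#'
#' Runs [wilcoxon_de()] with each group label as the focal group and binds
#' the results.
#'
#' @inheritParams wilcoxon_de
#' @return Combined data.frame over all groups.
#' @export
wilcoxon_de_all <- function(normalized, groups, min_pct = 0.25,
                            min_logfc = 0.25, alpha = 0.05) {
  if (is.null(names(groups))) names(groups) <- rownames(normalized)
  res <- lapply(sort(unique(groups)), function(g)
    wilcoxon_de(normalized, groups, g, min_pct, min_logfc, alpha))
  do.call(rbind, res)
}

#' Select highly variable genes
#'
#' Ranks genes by variance of the normalized values and returns the top `n`
#' (all genes if fewer exist). Constant genes are never selected while any
#' varying gene remains.
#'
#' @param normalized Normalized matrix, cells x genes.
#' @param n Number of genes to select (default 3000).
#' @return Character vector of gene names, in decreasing variance order.
#' @export
select_hvg <- function(normalized, n = 3000) {
  stopifnot(n >= 1)
  v <- apply(normalized, 2, stats::var)
  ord <- order(-v, seq_along(v))
  if (n < length(v) && any(v[ord[seq_len(n)]] == 0))
    ord <- c(ord[v[ord] > 0], ord[v[ord] == 0])
  colnames(normalized)[ord[seq_len(min(n, length(v)))]]
}

#' Write a differential-expression table
#'
#' @param de Output of [wilcoxon_de()] / [wilcoxon_de_all()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  data.table::fwrite(de, path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}
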