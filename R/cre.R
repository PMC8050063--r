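## Proximity-based cis-regulatory element prediction: link a cell-type-
## specific peak (DAP) to a cell-type-specific gene (DEG) when (1) both are
## specific in the same cell type, (2) any part of the peak lies within the
## +/- window of the gene's TSS (nearer-edge convention), and (3) the peak
## does not directly overlap the TSS (single-base test against the half-open
## peak).

#' Link cell-type-specific peaks to cell-type-specific genes
#'
#' @param daps A [call_cell_type_specific_peaks()] result, or a data.frame of
#'   specific peaks with columns `peak`, `cell_type`, `chrom`, `start`, `end`.
#' @param degs A [wilcoxon_de_all()]-style data.frame; only rows with
#'   `significant == TRUE` (if present) are used. Needs columns `gene` and
#'   `group`.
#' @param genes A [gene_models()] object covering every DEG gene.
#' @param window Maximum distance from the nearer peak edge to the TSS
#'   (default 100 kb).
#' @return data.frame of links: `gene`, `peak`, `cell_type`, `chrom`,
#'   `start`, `end`, `distance` (signed, negative when the peak lies upstream
#'   of the TSS in the gene's orientation; 0 only for a peak abutting the
#'   TSS).
#' @export
link_daps_to_degs <- function(daps, degs, genes, window = 100000) {
  stopifnot(inherits(genes, "gene_models"), window > 0)
  pk <- if (inherits(daps, "dap_result")) daps$calls else daps
  stopifnot(all(c("peak", "cell_type", "chrom", "start", "end") %in% names(pk)))
  if (nrow(pk) && anyNA(pk$start))
    stop("specific-peak table lacks coordinates; pass peaks= to the DAP caller")
  dg <- degs
  if (!is.null(dg$significant)) dg <- dg[dg$significant, , drop = FALSE]
  stopifnot(all(c("gene", "group") %in% names(dg)))
  dg <- unique(dg[, c("gene", "group")])
  missing <- setdiff(dg$gene, genes$genes$gene_id)
  if (length(missing))
    stop("DEG genes absent from gene models: ",
         paste(head(missing, 10), collapse = ", "))
  gi <- genes$genes[match(dg$gene, genes$genes$gene_id), ]
  out <- list()
  for (i in seq_len(nrow(dg))) {
    cand <- pk[pk$cell_type == dg$group[i] & pk$chrom == gi$chrom[i], ,
               drop = FALSE]
    if (nrow(cand) == 0) next
    tss <- gi$tss[i]
    contains <- cand$start <= tss & tss < cand$end
    gap <- ifelse(tss >= cand$end, tss - cand$end, cand$start - tss)
    keep <- !contains & gap <= window
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    gap <- gap[keep]
    upstream <- if (gi$strand[i] == "+") tss >= cand$end else cand$start > tss
    out[[length(out) + 1]] <- data.frame(
      gene = dg$gene[i], peak = cand$peak, cell_type = dg$group[i],
      chrom = cand$chrom, start = cand$start, end = cand$end,
      distance = ifelse(upstream, -gap, gap), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(), peak = character(),
                      cell_type = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      distance = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$cell_type, res$gene, res$chrom, res$start), ]
  rownames(res) <- NULL
  res
}

#' Write the CRE link table
#'
#' @param links Output of [link_daps_to_degs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cre_table <- function(links, path) {
  data.table::fwrite(links, path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}
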