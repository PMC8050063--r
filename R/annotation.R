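## Genomic element stratification, nearest-gene annotation and GWAS SNP to
## cell-type mapping. Each peak receives exactly one element class under the
## fixed priority exon > 5'UTR > 3'UTR > intron > promoter > distal; promoter
## means the strand-aware 5 kb (configurable) upstream of the TSS, intron is
## the transcript span minus the exon union of the owning gene.

ELEMENT_PRIORITY <- c("exon", "utr5", "utr3", "intron", "promoter")

#' Element interval sets derived from gene models
#'
#' @param genes A [gene_models()] object.
#' @param promoter_upstream Promoter length upstream of the TSS (bases).
#' @return Named list of interval data.frames: `exon`, `utr5`, `utr3`,
#'   `intron`, `promoter`.
#' @export
gene_element_sets <- function(genes, promoter_upstream = 5000) {
  stopifnot(inherits(genes, "gene_models"))
  span <- data.frame(chrom = genes$genes$chrom, start = genes$genes$start,
                     end = genes$genes$end, name = genes$genes$gene_id,
                     stringsAsFactors = FALSE)
  exon <- gene_sub_intervals(genes, "exons")
  intron <- if (nrow(exon) > 0) {
    d <- GenomicRanges::setdiff(
      intervals_to_granges(span),
      intervals_to_granges(exon))
    granges_to_intervals(d)
  } else span[, c("chrom", "start", "end")]
  list(exon = exon,
       utr5 = gene_sub_intervals(genes, "utr5"),
       utr3 = gene_sub_intervals(genes, "utr3"),
       intron = intron,
       promoter = promoter_windows(genes, upstream = promoter_upstream))
}

#' Classify peaks against explicit element interval sets
#'
#' Assigns each peak the highest-priority element class it overlaps
#' (exon > 5'UTR > 3'UTR > intron > promoter), or `distal` when it overlaps
#' none.
#'
#' @param peaks Interval data.frame.
#' @param elements Named list of interval data.frames as returned by
#'   [gene_element_sets()] (entries may be empty data.frames).
#' @return Factor of classes, one per peak, levels
#'   exon/utr5/utr3/intron/promoter/distal.
#' @export
classify_by_elements <- function(peaks, elements) {
  validate_intervals(peaks)
  cls <- rep("distal", nrow(peaks))
  pk <- intervals_to_granges(peaks)
  for (el in rev(ELEMENT_PRIORITY)) {    # low priority first, high overwrites
    x <- elements[[el]]
    if (is.null(x) || nrow(x) == 0) next
    hit <- GenomicRanges::countOverlaps(pk, intervals_to_granges(x)) > 0
    cls[hit] <- el
  }
  factor(cls, levels = c(ELEMENT_PRIORITY, "distal"))
}

#' Stratify peaks into genomic element classes
#'
#' @param peaks Interval data.frame.
#' @param genes A [gene_models()] object.
#' @param promoter_upstream Promoter length upstream of the TSS (default 5 kb;
#'   the 2 kb variant gives a subset of the promoter class, never moving a
#'   promoter peak to distal).
#' @return Factor of element classes, one per peak.
#' @export
classify_peak_elements <- function(peaks, genes, promoter_upstream = 5000) {
  classify_by_elements(peaks, gene_element_sets(genes, promoter_upstream))
}

#' Nearest gene (by TSS) for genomic positions
#'
#' For each position returns the gene minimizing `|position - TSS|` on the
#' same chromosome. Distance is signed by the gene's orientation: negative
#' when the position lies upstream of the TSS. Ties are broken by smaller TSS
#' coordinate, then lexicographic gene id.
#'
#' @param positions data.frame with columns `chrom` and `pos` (0-based), or an
#'   interval data.frame whose `start` is taken as the position.
#' @param genes A [gene_models()] object.
#' @return data.frame: `gene_id`, `distance`, `hit` (`FALSE` with NA fields
#'   when no gene lies on the position's chromosome).
#' @export
nearest_gene <- function(positions, genes) {
  stopifnot(inherits(genes, "gene_models"))
  if (is.null(positions$pos)) positions$pos <- positions$start
  g <- genes$genes[order(genes$genes$tss, genes$genes$gene_id), ]
  out <- data.frame(gene_id = rep(NA_character_, nrow(positions)),
                    distance = rep(NA_real_, nrow(positions)),
                    hit = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(positions$chrom)) {
    gi <- g[g$chrom == ch, , drop = FALSE]
    qi <- which(positions$chrom == ch)
    if (nrow(gi) == 0) next
    for (i in qi) {
      d <- abs(positions$pos[i] - gi$tss)
      j <- which.min(d)                  # tss/gene_id order breaks ties
      signed <- if (gi$strand[j] == "+") positions$pos[i] - gi$tss[j]
      else gi$tss[j] - positions$pos[i]
      out$gene_id[i] <- gi$gene_id[j]
      out$distance[i] <- signed
      out$hit[i] <- TRUE
    }
  }
  out
}

#' Overlap GWAS SNPs with peaks and attribute cell types
#'
#' Each SNP (single-base BED interval, post-liftover) is intersected with the
#' peak universe under the half-open point-in-interval test. When an
#' overlapping peak was called cell-type-specific, those cell types are
#' attributed to the SNP. The nearest gene (by TSS) is annotated for every
#' SNP.
#'
#' @param snps Interval data.frame of single-base SNPs (with `name`).
#' @param peaks Interval data.frame of merged peaks (with `name`).
#' @param daps Optional [call_cell_type_specific_peaks()] result or a
#'   data.frame with columns `peak` and `cell_type`.
#' @param genes A [gene_models()] object.
#' @return data.frame: `snp`, `chrom`, `pos`, `peaks` (comma-joined, "" if
#'   none), `in_peak`, `cell_types` (comma-joined, "" unless an overlapping
#'   peak is a DAP), `nearest_gene`, `tss_distance`.
#' @export
overlap_snps_with_peaks <- function(snps, peaks, daps = NULL, genes) {
  validate_intervals(snps); validate_intervals(peaks)
  if (is.null(snps$name)) snps$name <- interval_names(snps)
  if (is.null(peaks$name)) peaks$name <- interval_names(peaks)
  spec <- NULL
  if (!is.null(daps)) {
    spec <- if (inherits(daps, "dap_result")) daps$calls else daps
    stopifnot(all(c("peak", "cell_type") %in% names(spec)))
  }
  hits <- GenomicRanges::findOverlaps(intervals_to_granges(snps),
                                      intervals_to_granges(peaks))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  pk_str <- vapply(seq_len(nrow(snps)), function(i)
    paste(peaks$name[sh[qh == i]], collapse = ","), character(1))
  ct_str <- vapply(seq_len(nrow(snps)), function(i) {
    if (is.null(spec)) return("")
    ct <- sort(unique(spec$cell_type[spec$peak %in% peaks$name[sh[qh == i]]]))
    paste(ct, collapse = ",")
  }, character(1))
  ng <- nearest_gene(data.frame(chrom = snps$chrom, pos = snps$start), genes)
  data.frame(snp = snps$name, chrom = snps$chrom, pos = snps$start,
             peaks = pk_str, in_peak = nzchar(pk_str), cell_types = ct_str,
             nearest_gene = ng$gene_id, tss_distance = ng$distance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the SNP-peak overlap table
#'
#' @param x Output of [overlap_snps_with_peaks()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_snp_overlap_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}
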