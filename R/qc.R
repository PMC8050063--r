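## Per-cell quality control. ATAC cells are characterized by unique fragment
## count, promoter ratio and mitochondrial ratio; RNA cells by detected gene
## count and mitochondrial percentage. Filter bounds follow the study design:
## fragment counts kept inclusively in [1000, 40000], ratio exclusions strict
## ("less than 10%", "promoter ratio < 20%", "< 200 or > 3000 expressed
## genes", "mitochondrial gene percentages > 50 ... excluded").

#' QC thresholds
#'
#' @param atac_min_fragments,atac_max_fragments Inclusive bounds on unique
#'   fragments per ATAC cell.
#' @param atac_max_mito_ratio Cells with mitochondrial fragment ratio at or
#'   above this are removed (strict keep-if-below).
#' @param atac_min_promoter_ratio Cells below this promoter ratio are removed
#'   (keep-if-at-or-above).
#' @param rna_min_genes,rna_max_genes Inclusive bounds on detected genes per
#'   RNA cell.
#' @param rna_max_mito_percent Cells strictly above this mitochondrial
#'   percentage are removed (so exactly 50 is kept).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(atac_min_fragments = 1000, atac_max_fragments = 40000,
                          atac_max_mito_ratio = 0.10,
                          atac_min_promoter_ratio = 0.20,
                          rna_min_genes = 200, rna_max_genes = 3000,
                          rna_max_mito_percent = 50) {
  th <- structure(as.list(environment()), class = "qc_thresholds")
  if (th$atac_min_fragments >= th$atac_max_fragments ||
      th$rna_min_genes >= th$rna_max_genes)
    stop("paired QC bounds must satisfy min < max")
  th
}

#' Compute per-cell ATAC QC covariates
#'
#' Fragments identical in (chrom, start, end, barcode) are counted once
#' ("unique fragments"). The mitochondrial ratio is the fraction of a cell's
#' unique fragments on the designated mitochondrial chromosome; the promoter
#' ratio is the fraction overlapping any promoter interval. Both denominators
#' are all unique fragments of the cell.
#'
#' @param fragments Fragment data.frame (chrom, start, end, barcode).
#' @param promoters Interval data.frame of promoter windows (conventionally
#'   TSS +/- 2 kb, see [promoter_windows()]).
#' @param layout A [genome_layout()] naming the mitochondrial chromosome.
#' @return data.frame: barcode, n_fragments, promoter_ratio, mito_ratio.
#'   Barcodes with zero fragments do not appear.
#' @export
compute_atac_qc <- function(fragments, promoters, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  validate_intervals(promoters)
  dt <- data.table::as.data.table(
    fragments[, c("chrom", "start", "end", "barcode")])
  dt <- unique(dt, by = c("chrom", "start", "end", "barcode"))
  in_prom <- GenomicRanges::countOverlaps(
    intervals_to_granges(dt[, c("chrom", "start", "end")]),
    intervals_to_granges(promoters)) > 0
  dt[, `:=`(prom = in_prom, mito = chrom == layout$mito)]
  agg <- dt[, .(n_fragments = .N, promoter_ratio = mean(prom),
                mito_ratio = mean(mito)), by = barcode]
  data.table::setorder(agg, barcode)
  as.data.frame(agg)
}

#' Apply the ATAC cell filters
#'
#' Keeps a cell iff its unique fragment count lies in
#' `[atac_min_fragments, atac_max_fragments]` (inclusive), its mitochondrial
#' ratio is strictly below `atac_max_mito_ratio`, and its promoter ratio is at
#' least `atac_min_promoter_ratio`.
#'
#' @param qc Output of [compute_atac_qc()].
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of kept barcodes.
#' @export
filter_atac_cells <- function(qc, thresholds = qc_thresholds()) {
  f <- atac_qc_flags(qc, thresholds)
  f$barcode[f$pass]
}

#' Per-criterion ATAC QC pass/fail flags
#'
#' @inheritParams filter_atac_cells
#' @return data.frame: barcode, covariates, `pass_fragments`, `pass_mito`,
#'   `pass_promoter`, `pass` (conjunction).
#' @export
atac_qc_flags <- function(qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  out <- qc
  out$pass_fragments <- qc$n_fragments >= thresholds$atac_min_fragments &
    qc$n_fragments <= thresholds$atac_max_fragments
  out$pass_mito <- qc$mito_ratio < thresholds$atac_max_mito_ratio
  out$pass_promoter <- qc$promoter_ratio >= thresholds$atac_min_promoter_ratio
  out$pass <- out$pass_fragments & out$pass_mito & out$pass_promoter
  out
}

#' Compute per-cell RNA QC covariates
#'
#' @param counts Raw count matrix, cells x genes.
#' @param mito_genes Character vector of mitochondrial gene ids (possibly
#'   empty, giving 0% mito throughout).
#' @return data.frame: barcode, n_genes_detected, mito_percent.
#' @export
compute_rna_qc <- function(counts, mito_genes = character()) {
  tot <- Matrix::rowSums(counts)
  mito <- if (length(mito_genes))
    Matrix::rowSums(counts[, intersect(colnames(counts), mito_genes),
                           drop = FALSE]) else 0
  data.frame(barcode = rownames(counts),
             n_genes_detected = Matrix::rowSums(counts > 0),
             mito_percent = ifelse(tot > 0, 100 * mito / tot, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply the RNA cell filters
#'
#' Keeps a cell iff `rna_min_genes <= n_genes_detected <= rna_max_genes` and
#' `mito_percent <= rna_max_mito_percent` (the exclusion bounds `< 200`,
#' `> 3000`, `> 50` are strict, so the boundary values themselves are kept).
#'
#' @param qc Output of [compute_rna_qc()].
#' @param thresholds A [qc_thresholds()].
#' @return Character vector of kept barcodes.
#' @export
filter_rna_cells <- function(qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  keep <- qc$n_genes_detected >= thresholds$rna_min_genes &
    qc$n_genes_detected <= thresholds$rna_max_genes &
    qc$mito_percent <= thresholds$rna_max_mito_percent
  qc$barcode[keep]
}

#' Write a QC table with pass/fail flags
#'
#' @param qc Output of [compute_atac_qc()].
#' @param thresholds A [qc_thresholds()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_table <- function(qc, thresholds, path) {
  data.table::fwrite(atac_qc_flags(qc, thresholds), path, sep = "\t",
                     quote = FALSE, scipen = 50)
  invisible(path)
}
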