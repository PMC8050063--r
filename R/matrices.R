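## Accessibility matrix builders. All matrices are cells x features, stored
## sparsely (dgCMatrix) with barcodes as rownames and `chrom:start-end`
## feature names; gene-activity matrices carry gene ids instead. Fragments
## are assigned to features by any-overlap of the full fragment interval.

feature_matrix <- function(fragments, features, barcodes = NULL,
                           binary = TRUE) {
  validate_intervals(features)
  if (is.null(barcodes)) barcodes <- sort(unique(fragments$barcode))
  nm <- if (!is.null(features$name)) features$name else interval_names(features)
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(fragments[, c("chrom", "start", "end")]),
    intervals_to_granges(features))
  i <- match(fragments$barcode[S4Vectors::queryHits(hits)], barcodes)
  j <- S4Vectors::subjectHits(hits)
  keep <- !is.na(i)
  m <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(length(barcodes), nrow(features)),
                            dimnames = list(barcodes, nm))
  if (binary) m@x[] <- 1
  methods::as(m, "CsparseMatrix")
}

#' Parse feature names of an accessibility matrix back to intervals
#'
#' @param m Matrix with `chrom:start-end` column names.
#' @return Interval data.frame with a `name` column.
#' @export
feature_intervals <- function(m) parse_interval_names(colnames(m))

#' Build the binarized cell-by-bin matrix
#'
#' Tiles the genome into `bin_size` windows, drops fragments on unknown
#' chromosomes or the mitochondrial chromosome, and sets entry (cell, bin) to
#' 1 iff at least one of the cell's fragments overlaps the bin (a fragment
#' spanning a bin boundary marks both bins).
#'
#' @param fragments Fragment data.frame (ideally already QC-filtered).
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bases (default 5 kb).
#' @return Sparse binary dgCMatrix, cells x bins; zero-row matrix for empty
#'   input.
#' @export
build_cell_bin_matrix <- function(fragments, layout, bin_size = 5000) {
  stopifnot(inherits(layout, "genome_layout"))
  keep_chrom <- setdiff(layout$chrom, layout$mito)
  fragments <- fragments[fragments$chrom %in% keep_chrom, , drop = FALSE]
  bins <- bin_genome(layout, bin_size)
  bins <- bins[bins$chrom %in% keep_chrom, , drop = FALSE]
  feature_matrix(fragments, bins, binary = TRUE)
}

#' Remove hyper-accessible and blacklisted bins
#'
#' Drops the `floor(top_fraction * n_bins)` bins with the largest column sums
#' (ties at the cutoff resolved by genomic order, i.e. column order) and any
#' bin overlapping a blacklist interval. Rows are never removed.
#'
#' @param m Binary cell-by-bin matrix from [build_cell_bin_matrix()].
#' @param top_fraction Fraction of most accessible bins to drop (default 5%).
#' @param blacklist Optional interval data.frame of regions to exclude.
#' @return The filtered matrix.
#' @export
filter_bins <- function(m, top_fraction = 0.05, blacklist = NULL) {
  stopifnot(top_fraction >= 0, top_fraction < 1)
  n <- ncol(m)
  k <- floor(top_fraction * n)
  drop_top <- if (k > 0) order(-Matrix::colSums(m), seq_len(n))[seq_len(k)]
  else integer()
  drop_blk <- integer()
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    feats <- feature_intervals(m)
    drop_blk <- which(GenomicRanges::countOverlaps(
      intervals_to_granges(feats), intervals_to_granges(blacklist)) > 0)
  }
  keep <- setdiff(seq_len(n), union(drop_top, drop_blk))
  m[, keep, drop = FALSE]
}

#' Build the binarized cell-by-peak matrix
#'
#' Entry (cell, peak) is 1 iff at least one of the cell's fragments overlaps
#' the peak. Peaks must be disjoint; merge them first.
#'
#' @param fragments Fragment data.frame.
#' @param peaks Disjoint interval data.frame (see [merge_intervals()]).
#' @param barcodes Optional barcode universe fixing the row set and order.
#' @return Sparse binary dgCMatrix, cells x peaks.
#' @export
build_cell_peak_matrix <- function(fragments, peaks, barcodes = NULL) {
  validate_intervals(peaks)
  o <- order(peaks$chrom, peaks$start)
  po <- peaks[o, ]
  same <- po$chrom[-nrow(po)] == po$chrom[-1]
  if (nrow(po) > 1 && any(same & po$end[-nrow(po)] > po$start[-1]))
    stop("peaks overlap; apply merge_intervals() before building the matrix")
  feature_matrix(fragments, peaks, barcodes = barcodes, binary = TRUE)
}

#' Build a gene activity score matrix
#'
#' Counts, per (cell, gene), the cell's fragments overlapping the gene's
#' scoring window: the transcript span (`"transcript_overlap"`) or the span
#' extended `upstream` bases upstream of the strand-aware TSS
#' (`"body_plus_upstream"`, the 2 kb-upstream convention). A fragment may
#' count toward several genes.
#'
#' @param fragments Fragment data.frame.
#' @param genes A [gene_models()] object.
#' @param mode Scoring window flavour.
#' @param upstream Upstream extension for `"body_plus_upstream"`.
#' @param barcodes Optional barcode universe.
#' @return Sparse integer dgCMatrix, cells x genes.
#' @export
build_gene_activity_matrix <- function(fragments, genes,
                                       mode = c("transcript_overlap",
                                                "body_plus_upstream"),
                                       upstream = 2000, barcodes = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genes, "gene_models"), upstream >= 0)
  g <- genes$genes
  win <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                    name = g$gene_id, stringsAsFactors = FALSE)
  if (mode == "body_plus_upstream") {
    plus <- g$strand == "+"
    win$start <- ifelse(plus, pmax(g$start - upstream, 0), g$start)
    win$end <- ifelse(plus, g$end, g$end + upstream)
  }
  feature_matrix(fragments, win, barcodes = barcodes, binary = FALSE)
}

#' Aggregate fragments into a pseudobulk bin profile
#'
#' Tiles the genome into `bin_size` windows, drops the excluded chromosomes
#' (by default sex chromosomes and the mitochondrial chromosome) and counts
#' fragments per bin across all cells. Each fragment is counted exactly once,
#' in the bin containing its start position, so per-bin counts sum to the
#' number of retained fragments.
#'
#' @param fragments Fragment data.frame.
#' @param layout A [genome_layout()].
#' @param bin_size Bin width (default 10 kb).
#' @param exclude Chromosomes to exclude.
#' @return An object of class `pseudobulk_profile`: a data.frame of bins with
#'   a `count` column (zero-count bins retained so profiles align).
#' @export
build_pseudobulk_profile <- function(fragments, layout, bin_size = 10000,
                                     exclude = c(layout$sex, layout$mito)) {
  stopifnot(inherits(layout, "genome_layout"))
  bins <- bin_genome(layout, bin_size)
  bins <- bins[!bins$chrom %in% exclude, , drop = FALSE]
  fragments <- fragments[fragments$chrom %in% unique(bins$chrom), ,
                         drop = FALSE]
  key <- paste0(fragments$chrom, ":", floor(fragments$start / bin_size))
  bkey <- paste0(bins$chrom, ":", floor(bins$start / bin_size))
  tab <- table(factor(key, levels = bkey))
  bins$count <- as.numeric(tab)
  rownames(bins) <- NULL
  structure(bins, class = c("pseudobulk_profile", "data.frame"),
            bin_size = bin_size, excluded = exclude)
}

#' Write a sparse matrix as MTX with sidecar label files
#'
#' Writes `<prefix>.mtx`, `<prefix>.barcodes.tsv` (rownames) and
#' `<prefix>.features.tsv` (colnames).
#'
#' @param m Matrix with dimnames.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_mtx <- function(m, prefix) {
  Matrix::writeMM(methods::as(m, "CsparseMatrix"), paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".barcodes.tsv"))
  writeLines(colnames(m), paste0(prefix, ".features.tsv"))
  invisible(prefix)
}

#' Read a matrix written by [write_mtx()]
#'
#' @param prefix Path prefix.
#' @return Sparse dgCMatrix with dimnames restored.
#' @export
read_mtx <- function(prefix) {
  m <- Matrix::readMM(paste0(prefix, ".mtx"))
  dimnames(m) <- list(readLines(paste0(prefix, ".barcodes.tsv")),
                      readLines(paste0(prefix, ".features.tsv")))
  methods::as(m, "CsparseMatrix")
}
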