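## Gene models: strand, TSS, transcript span and exon/UTR structure.
## One model per gene. Coordinates follow the package-wide 0-based half-open
## convention; GTF input (1-based inclusive) is converted at the boundary.

#' Construct a set of gene models
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (transcript span, half-open). The TSS is
#'   derived from the strand: `start` for `+` genes, `end - 1` for `-` genes.
#' @param exons,utr5,utr3 data.frames with columns `gene_id`, `start`, `end`
#'   (chromosome implied by the gene); may be empty. All intervals must lie
#'   within the owning gene's span.
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (including a derived `tss` column), `exons`, `utr5`, `utr3`.
#' @export
gene_models <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  if (any(genes$start >= genes$end)) stop("gene span must satisfy start < end")
  genes$gene_id <- as.character(genes$gene_id)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  empty <- data.frame(gene_id = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE)
  fix_sub <- function(x, what) {
    if (is.null(x) || nrow(x) == 0) return(empty)
    stopifnot(all(c("gene_id", "start", "end") %in% names(x)))
    x <- x[, c("gene_id", "start", "end")]
    x$gene_id <- as.character(x$gene_id)
    i <- match(x$gene_id, genes$gene_id)
    if (anyNA(i)) stop(what, " refers to unknown gene_id")
    if (any(x$start < genes$start[i] | x$end > genes$end[i]))
      stop(what, " intervals must lie within the gene span")
    if (any(x$start >= x$end)) stop(what, " intervals must satisfy start < end")
    x
  }
  structure(list(genes = genes,
                 exons = fix_sub(exons, "exon"),
                 utr5 = fix_sub(utr5, "utr5"),
                 utr3 = fix_sub(utr3, "utr3")),
            class = "gene_models")
}

#' @method print gene_models
#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ", nrow(x$exons), " exons, ",
      nrow(x$utr5), " 5'UTRs, ", nrow(x$utr3), " 3'UTRs\n", sep = "")
  invisible(x)
}

gene_sub_intervals <- function(gm, which) {
  sub <- gm[[which]]
  i <- match(sub$gene_id, gm$genes$gene_id)
  data.frame(chrom = gm$genes$chrom[i], start = sub$start, end = sub$end,
             name = sub$gene_id, stringsAsFactors = FALSE)
}

#' Strand-aware promoter windows
#'
#' One window per gene: `upstream` bases upstream of the TSS plus `downstream`
#' bases from the TSS onward (both in the gene's orientation), clipped at
#' chromosome start. With `downstream = 0` the window is upstream-only, the
#' convention used for element stratification; QC promoter windows use
#' `upstream = downstream = 2000`.
#'
#' @param gm A [gene_models()] object.
#' @param upstream,downstream Non-negative widths in bases
#'   (`upstream + downstream > 0`).
#' @return Interval data.frame with `name` = gene id.
#' @export
promoter_windows <- function(gm, upstream = 5000, downstream = 0) {
  stopifnot(inherits(gm, "gene_models"), upstream >= 0, downstream >= 0,
            upstream + downstream > 0)
  g <- gm$genes
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss + 1 - downstream)
  end <- ifelse(plus, g$tss + downstream, g$tss + 1 + upstream)
  data.frame(chrom = g$chrom, start = pmax(start, 0), end = end,
             name = g$gene_id, stringsAsFactors = FALSE)
}

#' Write gene models to the tabular dialect
#'
#' A single TSV with header and columns gene_id, chrom, strand, feature
#' (`transcript`/`exon`/`utr5`/`utr3`), start, end, in half-open 0-based
#' coordinates. [read_gene_models_tab()] round-trips this format.
#'
#' @param gm A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_tab <- function(gm, path) {
  stopifnot(inherits(gm, "gene_models"))
  g <- gm$genes
  rows <- list(data.frame(gene_id = g$gene_id, chrom = g$chrom,
                          strand = g$strand, feature = "transcript",
                          start = g$start, end = g$end, stringsAsFactors = FALSE))
  for (w in c("exons", "utr5", "utr3")) {
    sub <- gm[[w]]
    if (nrow(sub) == 0) next
    i <- match(sub$gene_id, g$gene_id)
    rows[[length(rows) + 1]] <-
      data.frame(gene_id = sub$gene_id, chrom = g$chrom[i],
                 strand = g$strand[i],
                 feature = c(exons = "exon", utr5 = "utr5", utr3 = "utr3")[[w]],
                 start = sub$start, end = sub$end, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$feature != "transcript", out$start), ]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}

#' Read gene models from the tabular dialect
#'
#' @param path TSV written by [write_gene_models_tab()].
#' @return A [gene_models()] object.
#' @export
read_gene_models_tab <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("gene_id", "chrom", "strand", "feature", "start", "end")
  if (!all(need %in% names(df))) stop("missing columns in gene model table")
  tr <- df[df$feature == "transcript", ]
  gene_models(genes = tr[, c("gene_id", "chrom", "strand", "start", "end")],
              exons = df[df$feature == "exon", c("gene_id", "start", "end")],
              utr5 = df[df$feature == "utr5", c("gene_id", "start", "end")],
              utr3 = df[df$feature == "utr3", c("gene_id", "start", "end")])
}

#' Read gene models from a GTF file
#'
#' Uses transcript/exon/five_prime_utr/three_prime_utr records (1-based
#' inclusive, converted to half-open here). Requires one transcript per gene;
#' for multi-transcript GTFs pre-filter to a canonical transcript.
#'
#' @param path GTF file path.
#' @return A [gene_models()] object.
#' @export
read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_models_gtf requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  df$start <- df$start - 1  # to half-open
  type <- as.character(df$type)
  gid <- as.character(df$gene_id)
  tr <- df[type == "transcript", ]
  if (anyDuplicated(tr$gene_id))
    stop("GTF contains multiple transcripts per gene; pre-filter to one")
  pick <- function(what) {
    sub <- df[type %in% what, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    data.frame(gene_id = as.character(sub$gene_id), start = sub$start,
               end = sub$end, stringsAsFactors = FALSE)
  }
  gene_models(
    genes = data.frame(gene_id = as.character(tr$gene_id),
                       chrom = as.character(tr$seqnames),
                       strand = as.character(tr$strand),
                       start = tr$start, end = tr$end, stringsAsFactors = FALSE),
    exons = pick("exon"),
    utr5 = pick(c("five_prime_utr", "5UTR")),
    utr3 = pick(c("three_prime_utr", "3UTR")))
}
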