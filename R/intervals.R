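## Genomic interval engine. All coordinates are 0-based half-open [start, end)
## (BED convention); 1-based inclusive inputs (GTF-style) are converted at the
## reader boundary. Interval sets are plain data.frames with columns
## chrom / start / end (+ optional name); GenomicRanges does the heavy lifting
## internally, with the +1 shift confined to the two converters below.

#' Construct a set of genomic intervals
#'
#' Builds a validated data.frame of 0-based half-open intervals.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends; must satisfy `start < end`.
#' @param name Optional identifiers (recycled if length 1).
#' @return A data.frame with columns `chrom`, `start`, `end` and, if supplied,
#'   `name`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- rep_len(as.character(name), nrow(df))
  validate_intervals(df)
  df
}

#' Validate an interval data.frame
#'
#' Checks the half-open interval invariants: non-empty chromosome names,
#' `0 <= start < end`, finite coordinates.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_intervals <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(!nzchar(x$chrom) | is.na(x$chrom)))
    stop("interval chromosome names must be non-empty")
  if (any(!is.finite(x$start) | !is.finite(x$end)))
    stop("interval coordinates must be finite")
  if (any(x$start < 0)) stop("interval starts must be >= 0")
  if (any(x$start >= x$end)) stop("intervals must satisfy start < end (half-open)")
  invisible(x)
}

#' Describe a genome as an ordered set of chromosomes
#'
#' @param chrom Character vector of unique chromosome names, in the order they
#'   should appear in all outputs.
#' @param length Integer vector of chromosome lengths (bases), all `> 0`.
#' @param mito Name of the mitochondrial chromosome (need not be present in
#'   `chrom`, but usually is).
#' @param sex Character vector of sex chromosome names (possibly empty).
#' @return An object of class `genome_layout`.
#' @export
genome_layout <- function(chrom, length, mito = "chrM",
                          sex = c("chrX", "chrY")) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (any(length <= 0)) stop("all chromosome lengths must be > 0")
  structure(list(chrom = chrom, length = stats::setNames(length, chrom),
                 mito = mito, sex = intersect(sex, chrom)),
            class = "genome_layout")
}

#' @method print genome_layout
#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom), " chromosomes, ",
      format(sum(x$length), big.mark = ","), " bases; mito=", x$mito,
      if (length(x$sex)) paste0("; sex=", paste(x$sex, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

## BED half-open <-> GRanges 1-based closed converters. Every GRanges
## round-trip in the package goes through these two functions.
intervals_to_granges <- function(x, layout = NULL) {
  validate_intervals(x)
  seqlev <- if (!is.null(layout)) layout$chrom else sort(unique(x$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlev),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

granges_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Test whether two intervals overlap
#'
#' Half-open semantics: `[0,100)` and `[100,200)` do not overlap.
#' Vectorized over both arguments.
#'
#' @param a,b Interval data.frames (see [genomic_intervals()]), recycled to a
#'   common length.
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n); bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] & a$start[ai] < b$end[bi] & b$start[bi] < a$end[ai]
}

#' Merge overlapping and book-ended intervals
#'
#' Returns the minimal sorted set of disjoint intervals covering the same
#' bases. Book-ended intervals (gap 0, e.g. `[0,10)` + `[10,20)`) are merged,
#' matching the default interval-reduction semantics used to build merged peak
#' universes.
#'
#' @param x Interval data.frame.
#' @return Interval data.frame sorted by (chrom, start); empty input gives an
#'   empty output. Names are not propagated.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr <- GenomicRanges::reduce(intervals_to_granges(x))
  gr <- GenomicRanges::sort(gr)
  granges_to_intervals(gr)
}

#' Tile a genome into fixed-size bins
#'
#' Per chromosome, contiguous tiles `[0,b), [b,2b), ...`; the final tile is
#' truncated at the chromosome length. Order follows the layout.
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bases, `> 0`.
#' @return Interval data.frame with a `name` column `chrom:start-end`.
#' @export
bin_genome <- function(layout, bin_size) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a single positive number")
  pieces <- lapply(layout$chrom, function(ch) {
    len <- layout$length[[ch]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$name <- interval_names(out)
  rownames(out) <- NULL
  out
}

interval_names <- function(x) sprintf("%s:%d-%d", x$chrom, x$start, x$end)

parse_interval_names <- function(nm) {
  m <- regmatches(nm, regexec("^(.+):([0-9]+)-([0-9]+)$", nm))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed interval name(s): ", paste(nm[bad][1], collapse = ", "))
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.numeric(vapply(m, `[`, "", 3L)),
             end = as.numeric(vapply(m, `[`, "", 4L)),
             name = nm, stringsAsFactors = FALSE)
}

#' Nearest anchored feature for each query
#'
#' For each query (point or interval) returns the feature minimizing the
#' absolute distance between the query and the feature's anchor point
#' (e.g. a TSS). Distance is 0 when the query contains the anchor; otherwise
#' it is signed positive when the query lies at higher genomic coordinates
#' than the anchor. Ties are broken by smaller feature start, then
#' lexicographic feature name.
#'
#' @param query Interval data.frame; represent points as width-1 intervals.
#' @param features Interval data.frame with `name` and an `anchor` column
#'   (defaults to `start` if absent).
#' @return data.frame with one row per query: `feature`, `distance`, `hit`
#'   (`FALSE` when the query's chromosome carries no feature; `feature` is NA
#'   and `distance` NA then).
#' @export
nearest_feature <- function(query, features) {
  validate_intervals(query)
  validate_intervals(features)
  if (nrow(features) == 0) stop("features must be non-empty")
  if (is.null(features$anchor)) features$anchor <- features$start
  if (is.null(features$name)) features$name <- interval_names(features)
  out <- data.frame(feature = rep(NA_character_, nrow(query)),
                    distance = rep(NA_real_, nrow(query)),
                    hit = rep(FALSE, nrow(query)), stringsAsFactors = FALSE)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fs <- features[features$chrom == ch, , drop = FALSE]
    if (nrow(fs) == 0) next
    ## deterministic preference order for ties: smaller start, then name
    fs <- fs[order(fs$start, fs$name), , drop = FALSE]
    for (i in qi) {
      s <- query$start[i]; e <- query$end[i]
      d <- ifelse(fs$anchor >= s & fs$anchor < e, 0,
                  ifelse(fs$anchor < s, s - fs$anchor, (e - 1) - fs$anchor))
      j <- which.min(abs(d))   # first minimum respects the tie order
      out$feature[i] <- fs$name[j]
      out$distance[i] <- d[j]
      out$hit[i] <- TRUE
    }
  }
  out
}

#' Read a BED3/BED4 file
#'
#' Tab-separated, no header; columns chrom, start, end and optionally name.
#'
#' @param path File path (plain or gzipped).
#' @return Interval data.frame.
#' @export
read_bed <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          data.table = FALSE)
  if (ncol(df) < 3) stop("BED file must have at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df <- df[, seq_len(min(ncol(df), 4)), drop = FALSE]
  df$chrom <- as.character(df$chrom)
  validate_intervals(df)
  df
}

#' Write intervals as BED3/BED4
#'
#' @param x Interval data.frame; the `name` column, if present, becomes the
#'   fourth BED column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end", if (!is.null(x$name)) "name")
  data.table::fwrite(x[, cols, drop = FALSE], path, sep = "\t",
                     col.names = FALSE, quote = FALSE, scipen = 50)
  invisible(path)
}
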