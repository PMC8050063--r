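## Synthetic study generator. Emits a fully self-contained single-cell
## multi-omic study -- ATAC fragments, RNA counts, gene models, trajectory,
## GWAS SNPs -- with recorded ground truth (planted cell-type-specific peaks,
## marker genes, peak-gene couples, stage-transition events, SNP placements),
## so that every downstream stage has a recoverable answer key.
##
## All generators are deterministic under the config seed. Sub-generators use
## fixed offsets from it (truth +0, peak matrix +1, fragments +2, RNA +3,
## trajectory +4, stage matrix +5, SNPs +6, gene activity +7) so each piece is
## reproducible in isolation.

#' Default synthetic genome
#'
#' Five 10-Mb autosomes plus small sex chromosomes and a mitochondrial
#' chromosome; large enough that 1,000 non-overlapping peaks, 500 genes and
#' their promoter neighbourhoods fit without crowding.
#'
#' @return A [genome_layout()].
#' @export
default_genome_layout <- function() {
  genome_layout(
    chrom = c(paste0("chr", 1:5), "chrX", "chrY", "chrM"),
    length = c(rep(10e6, 5), 5e6, 2.5e6, 16299),
    mito = "chrM", sex = c("chrX", "chrY"))
}

#' Synthetic study configuration
#'
#' Holds every tunable constant of the emulated study design. Defaults define
#' the reference scenario used throughout the test-suite: 5 cell types x 200
#' cells, 1,000 peaks with 50 planted type-specific peaks per type, Bernoulli
#' accessibility `p0 = 0.05` (baseline) vs `p1 = 0.6` (planted), 20 planted
#' marker genes per type at log2 fold change 2, and a 15-stage branching
#' lineage with 10 transition peaks per edge.
#'
#' @param n_cell_types,n_cells_per_type,n_peaks,n_specific_peaks_per_type
#'   Study dimensions.
#' @param p0,p1 Baseline and elevated per-cell peak accessibility
#'   probabilities, `0 <= p0 < p1 <= 1`.
#' @param peak_width Peak width in bases.
#' @param n_genes,n_marker_genes_per_type Gene universe and planted markers
#'   (markers are coupled to same-type planted peaks within +/-100 kb of the
#'   TSS so the cis-regulatory linker has recoverable truth).
#' @param marker_log2_fold_change Planted marker elevation (log2).
#' @param rna_nb_mean,rna_nb_dispersion Negative-binomial mean and size for
#'   baseline RNA counts.
#' @param activity_mean Baseline Poisson mean for the simulated gene-activity
#'   modality.
#' @param fragment_total_meanlog,fragment_total_sdlog Log-normal parameters of
#'   per-cell fragment totals, clamped to `fragment_total_range`.
#' @param fragment_total_range Clamp range for per-cell totals of clean cells;
#'   chosen inside the 1,000--40,000 QC window so non-contaminant cells pass.
#' @param mito_fraction,promoter_fragment_fraction Per-cell fractions of
#'   fragments placed on the mitochondrial chromosome and inside QC promoter
#'   windows (TSS +/- 2 kb).
#' @param contaminant_fraction Fraction of extra cells planted to violate one
#'   QC rule each (low/high fragment count, high mito, low promoter ratio).
#' @param cre_window CRE linking window (bases) that planted couples must
#'   respect.
#' @param stage_graph A [stage_graph()]; defaults to [kidney_stage_graph()].
#' @param lineage_paths Named list of root-to-leaf stage paths; defaults to
#'   [kidney_lineage_paths()].
#' @param cells_per_stage,n_transition_peaks_per_edge Trajectory scenario
#'   sizes (each lineage receives `cells_per_stage * path length` cells; half
#'   of each edge's transition peaks open, half close).
#' @param n_snps,snp_in_peak_fraction GWAS scenario: total SNPs and the
#'   fraction placed inside planted type-specific peaks.
#' @param n_blacklist,blacklist_width Planted blacklist regions.
#' @param genome A [genome_layout()].
#' @param seed Integer master seed (< 2^31 - 8).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cell_types = 5, n_cells_per_type = 200,
                       n_peaks = 1000, n_specific_peaks_per_type = 50,
                       p0 = 0.05, p1 = 0.6, peak_width = 400,
                       n_genes = 500, n_marker_genes_per_type = 20,
                       marker_log2_fold_change = 2,
                       rna_nb_mean = 2, rna_nb_dispersion = 2,
                       activity_mean = 2,
                       fragment_total_meanlog = log(1500),
                       fragment_total_sdlog = 0.25,
                       fragment_total_range = c(1100, 30000),
                       mito_fraction = 0.03,
                       promoter_fragment_fraction = 0.35,
                       contaminant_fraction = 0.04,
                       cre_window = 100000,
                       stage_graph = kidney_stage_graph(),
                       lineage_paths = kidney_lineage_paths(),
                       cells_per_stage = 150,
                       n_transition_peaks_per_edge = 10,
                       n_snps = 200, snp_in_peak_fraction = 0.3,
                       n_blacklist = 5, blacklist_width = 10000,
                       genome = default_genome_layout(),
                       seed = 1L) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with(cfg, {
    if (!(p0 >= 0 && p0 < p1 && p1 <= 1))
      stop("accessibility rates must satisfy 0 <= p0 < p1 <= 1")
    counts <- c(n_cell_types, n_cells_per_type, n_peaks,
                n_specific_peaks_per_type, n_genes, n_marker_genes_per_type,
                cells_per_stage, n_transition_peaks_per_edge, n_snps,
                n_blacklist)
    if (any(counts < 0)) stop("all counts must be >= 0")
    probs <- c(mito_fraction, promoter_fragment_fraction,
               contaminant_fraction, snp_in_peak_fraction)
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    if (rna_nb_mean <= 0 || rna_nb_dispersion <= 0 || activity_mean <= 0)
      stop("RNA/activity parameters must be positive")
    if (n_marker_genes_per_type > n_specific_peaks_per_type)
      stop("need at least one planted peak per planted marker gene")
    if (n_cell_types * n_marker_genes_per_type > n_genes)
      stop("more planted markers than genes")
    if (!inherits(genome, "genome_layout")) stop("genome must be a genome_layout")
    if (!inherits(stage_graph, "stage_graph")) stop("stage_graph must be a stage_graph")
    if (abs(seed) >= 2^31 - 8) stop("seed too large")
  })
  invisible(cfg)
}

#' @method print sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cell_types, " types x ", x$n_cells_per_type,
      " cells, ", x$n_peaks, " peaks (", x$n_specific_peaks_per_type,
      " specific/type), p0=", x$p0, ", p1=", x$p1, ", seed=", x$seed, "\n",
      sep = "")
  invisible(x)
}

sim_autosomes <- function(layout) {
  setdiff(layout$chrom, c(layout$mito, layout$sex))
}

## Sample n disjoint width-w intervals on the autosomes, uniformly, avoiding
## `avoid` (with a 1-base gap so nothing merges away).
place_disjoint <- function(layout, n, width, avoid) {
  autos <- sim_autosomes(layout)
  lens <- layout$length[autos]
  placed <- avoid
  out <- vector("list", 0)
  remaining <- n
  guard <- 0
  while (remaining > 0) {
    guard <- guard + 1
    if (guard > 200) stop("could not place intervals in genome: too crowded")
    m <- remaining * 2
    ch <- sample(autos, m, replace = TRUE, prob = lens / sum(lens))
    st <- floor(runif(m, 1, lens[ch] - width - 1))
    cand <- data.frame(chrom = ch, start = st, end = st + width,
                       stringsAsFactors = FALSE)
    ## pad by 1 base so book-ended placements are rejected too
    pad <- cand; pad$start <- pad$start - 1; pad$end <- pad$end + 1
    hit_prev <- GenomicRanges::countOverlaps(
      intervals_to_granges(pad), intervals_to_granges(placed)) > 0
    self <- GenomicRanges::countOverlaps(
      intervals_to_granges(pad), intervals_to_granges(cand)) > 1
    ok <- which(!hit_prev & !self)
    if (length(ok) == 0) next
    take <- head(ok, remaining)
    out[[length(out) + 1]] <- cand[take, , drop = FALSE]
    placed <- rbind(placed[, c("chrom", "start", "end")],
                    cand[take, c("chrom", "start", "end")])
    remaining <- remaining - length(take)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

sim_gene_universe <- function(cfg) {
  autos <- sim_autosomes(cfg$genome)
  per <- diff(round(seq(0, cfg$n_genes, length.out = length(autos) + 1)))
  rows <- list(); exs <- list(); u5 <- list(); u3 <- list()
  gid <- 0
  for (k in seq_along(autos)) {
    nc <- per[k]
    if (nc == 0) next
    len <- cfg$genome$length[[autos[k]]]
    slot <- floor((len - 400000) / nc)
    for (i in seq_len(nc)) {
      gid <- gid + 1
      id <- sprintf("G%04d", gid)
      span <- sample(5000:20000, 1)
      s <- 200000 + (i - 1) * slot + floor(runif(1, 0, max(slot - span - 1, 1)))
      e <- s + span
      strand <- sample(c("+", "-"), 1)
      rows[[gid]] <- data.frame(gene_id = id, chrom = autos[k], strand = strand,
                                start = s, end = e, stringsAsFactors = FALSE)
      nex <- sample(2:4, 1)
      step <- floor(span / nex)
      for (j in seq_len(nex)) {
        es <- s + (j - 1) * step + 50
        ee <- es + sample(200:400, 1)
        exs[[length(exs) + 1]] <- data.frame(gene_id = id, start = es, end = ee)
      }
      first <- s + 50                      # TSS-side exon start on + strand
      lastj <- s + (nex - 1) * step + 50
      if (strand == "+") {
        u5[[length(u5) + 1]] <- data.frame(gene_id = id, start = first, end = first + 150)
        u3[[length(u3) + 1]] <- data.frame(gene_id = id, start = lastj, end = lastj + 150)
      } else {
        u5[[length(u5) + 1]] <- data.frame(gene_id = id, start = lastj, end = lastj + 150)
        u3[[length(u3) + 1]] <- data.frame(gene_id = id, start = first, end = first + 150)
      }
    }
  }
  gene_models(do.call(rbind, rows), do.call(rbind, exs),
              do.call(rbind, u5), do.call(rbind, u3))
}

#' Build the planted ground truth of a synthetic study
#'
#' Lays out gene models, the peak universe (marker-coupled planted peaks,
#' further type-specific peaks, null peaks, all disjoint and clear of QC
#' promoter windows), planted markers, cis couples, cells (with planted QC
#' violators) and blacklist regions. Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_truth`.
#' @export
build_truth <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  layout <- config$genome
  gm <- sim_gene_universe(config)
  types <- paste0("T", seq_len(config$n_cell_types))

  marker_pool <- sample(gm$genes$gene_id,
                        config$n_cell_types * config$n_marker_genes_per_type)
  markers <- data.frame(
    gene_id = marker_pool,
    cell_type = rep(types, each = config$n_marker_genes_per_type),
    stringsAsFactors = FALSE)

  ## QC promoter neighbourhoods are kept peak-free so that injected promoter
  ## fragments never contaminate planted peak accessibility rates.
  qc_prom <- promoter_windows(gm, upstream = 2000, downstream = 2000)
  avoid0 <- qc_prom[, c("chrom", "start", "end")]

  w <- config$peak_width
  linked <- vector("list", nrow(markers))
  placed <- avoid0
  for (i in seq_len(nrow(markers))) {
    g <- gm$genes[match(markers$gene_id[i], gm$genes$gene_id), ]
    repeat {
      off <- sample(5000:(config$cre_window - w - 5000), 1)
      side <- sample(c(-1, 1), 1)
      st <- if (side > 0) g$tss + off else g$tss - off - w
      cand <- data.frame(chrom = g$chrom, start = st, end = st + w)
      if (st < 1 || st + w >= layout$length[[g$chrom]]) next
      ## base-R any-overlap check with a 1-base pad against placed intervals
      if (!any(placed$chrom == g$chrom & placed$start < st + w + 1 &
               st - 1 < placed$end)) break
    }
    linked[[i]] <- cand
    placed <- rbind(placed, cand)
  }
  linked <- if (length(linked)) do.call(rbind, linked)
  else data.frame(chrom = character(), start = numeric(), end = numeric())
  linked$specific_type <- markers$cell_type
  linked$linked_gene <- markers$gene_id

  n_extra_spec <- config$n_cell_types *
    (config$n_specific_peaks_per_type - config$n_marker_genes_per_type)
  n_null <- config$n_peaks - nrow(linked) - n_extra_spec
  if (n_null < 0) stop("n_peaks too small for the planted structure")
  rest <- place_disjoint(layout, n_extra_spec + n_null, w, placed)
  rest$specific_type <- c(
    rep(types, each = config$n_specific_peaks_per_type -
          config$n_marker_genes_per_type),
    rep(NA_character_, n_null))
  rest$linked_gene <- NA_character_
  peaks <- rbind(linked, rest)
  o <- order(match(peaks$chrom, layout$chrom), peaks$start)
  peaks <- peaks[o, ]
  peaks$name <- sprintf("peak%04d", seq_len(nrow(peaks)))
  rownames(peaks) <- NULL

  links <- data.frame(
    gene_id = markers$gene_id,
    peak = peaks$name[match(markers$gene_id, peaks$linked_gene)],
    cell_type = markers$cell_type, stringsAsFactors = FALSE)
  pk <- peaks[match(links$peak, peaks$name), ]
  tss <- gm$genes$tss[match(links$gene_id, gm$genes$gene_id)]
  links$distance <- ifelse(tss >= pk$end, tss - pk$end, pk$start - tss)

  n_clean <- config$n_cell_types * config$n_cells_per_type
  cells <- data.frame(
    barcode = sprintf("BC%05d", seq_len(n_clean)),
    cell_type = rep(types, each = config$n_cells_per_type),
    qc_violation = "none", stringsAsFactors = FALSE)
  n_cont <- round(config$contaminant_fraction * n_clean)
  if (n_cont > 0) {
    modes <- rep_len(c("low_count", "high_count", "high_mito", "low_promoter"),
                     n_cont)
    cells <- rbind(cells, data.frame(
      barcode = sprintf("BC%05d", n_clean + seq_len(n_cont)),
      cell_type = sample(types, n_cont, replace = TRUE),
      qc_violation = modes, stringsAsFactors = FALSE))
  }

  blk <- place_disjoint(layout, config$n_blacklist, config$blacklist_width,
                        rbind(placed[, c("chrom", "start", "end")],
                              rest[, c("chrom", "start", "end")]))
  blk$name <- sprintf("blacklist%02d", seq_len(nrow(blk)))

  structure(list(config = config, layout = layout, genes = gm,
                 cell_types = types, markers = markers,
                 peaks = peaks[, c("chrom", "start", "end", "name",
                                   "specific_type", "linked_gene")],
                 links = links, cells = cells, blacklist = blk),
            class = "synthetic_truth")
}

#' @method print synthetic_truth
#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", nrow(x$cells), " cells (",
      sum(x$cells$qc_violation != "none"), " planted QC violators), ",
      nrow(x$peaks), " peaks (", sum(!is.na(x$peaks$specific_type)),
      " planted specific), ", nrow(x$markers), " planted markers, ",
      nrow(x$links), " planted cis couples\n", sep = "")
  invisible(x)
}

#' Peak universe of a synthetic truth as a BED-style interval set
#'
#' @param truth A [build_truth()] result.
#' @return Interval data.frame (chrom, start, end, name).
#' @export
truth_peak_intervals <- function(truth) {
  truth$peaks[, c("chrom", "start", "end", "name")]
}

## Bernoulli accessibility rates for a set of cells over the peak universe.
access_prob_matrix <- function(truth, cells) {
  cfg <- truth$config
  p <- matrix(cfg$p0, nrow(cells), nrow(truth$peaks),
              dimnames = list(cells$barcode, truth$peaks$name))
  for (t in truth$cell_types) {
    rows <- cells$cell_type == t
    cols <- !is.na(truth$peaks$specific_type) & truth$peaks$specific_type == t
    p[rows, cols] <- cfg$p1
  }
  p
}

#' Simulate a binarized cell-by-peak matrix directly
#'
#' Draws per-cell, per-peak Bernoulli accessibility at the planted rates,
#' skipping fragment generation. This is the fast substrate for
#' differential-accessibility recovery experiments; [simulate_atac_fragments()]
#' realizes the same statistical structure at fragment level.
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-built [build_truth()] result.
#' @param cells Which cells to simulate: `"clean"` (default, QC-passing only)
#'   or `"all"`.
#' @return List with `matrix` (sparse binary dgCMatrix, cells x peaks),
#'   `labels` (named cell-type vector) and `truth`.
#' @export
simulate_peak_matrix <- function(config, truth = NULL,
                                 cells = c("clean", "all")) {
  cells <- match.arg(cells)
  if (is.null(truth)) truth <- build_truth(config)
  set.seed(config$seed + 1L)
  cdf <- truth$cells
  if (cells == "clean") cdf <- cdf[cdf$qc_violation == "none", ]
  p <- access_prob_matrix(truth, cdf)
  x <- matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p),
              dimnames = dimnames(p))
  list(matrix = methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix"),
       labels = stats::setNames(cdf$cell_type, cdf$barcode),
       truth = truth)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate ATAC fragment records
#'
#' Realizes the planted accessibility structure as a 10x-style fragment table:
#' each accessible (cell, peak) pair emits >= 1 fragment inside the peak;
#' mitochondrial and promoter-window fragments are injected to hit the
#' configured per-cell QC covariates (promoter fragments favour each cell
#' type's planted marker genes, giving gene-activity scores genuine cell-type
#' signal); remaining fragments are placed uniformly outside peaks. Planted QC
#' violator cells break exactly one filter each. Identical config + seed gives
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @param truth Optional pre-built truth.
#' @return List with `fragments` (data.frame: chrom, start, end, barcode,
#'   count, position-sorted and deduplicated) and `truth`.
#' @export
simulate_atac_fragments <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- build_truth(config)
  cfg <- truth$config
  layout <- truth$layout
  set.seed(cfg$seed + 2L)
  cells <- truth$cells
  n <- nrow(cells)

  acc <- access_prob_matrix(truth, cells)
  acc <- matrix(stats::rbinom(length(acc), 1L, acc), nrow(acc), ncol(acc),
                dimnames = dimnames(acc))

  totals <- round(clamp(stats::rlnorm(n, cfg$fragment_total_meanlog,
                                      cfg$fragment_total_sdlog),
                        cfg$fragment_total_range[1], cfg$fragment_total_range[2]))
  totals[cells$qc_violation == "low_count"] <- 300
  totals[cells$qc_violation == "high_count"] <- 42000
  mito_frac <- rep(cfg$mito_fraction, n)
  mito_frac[cells$qc_violation == "high_mito"] <- 0.35
  prom_frac <- rep(cfg$promoter_fragment_fraction, n)
  prom_frac[cells$qc_violation == "low_promoter"] <- 0.04

  ## fragments realizing accessible (cell, peak) pairs
  idx <- which(acc == 1L, arr.ind = TRUE)
  per_pair <- 1L + stats::rpois(nrow(idx), 0.3)
  cell_i <- rep(idx[, 1], per_pair)
  peak_j <- rep(idx[, 2], per_pair)
  plen <- sample(60:150, length(cell_i), replace = TRUE)
  pst <- truth$peaks$start[peak_j] +
    floor(stats::runif(length(cell_i), 0,
                       truth$peaks$end[peak_j] - truth$peaks$start[peak_j] - plen))
  peak_frags <- data.table::data.table(
    chrom = truth$peaks$chrom[peak_j], start = pst, end = pst + plen,
    barcode = cells$barcode[cell_i])
  n_peak <- tabulate(cell_i, nbins = n)

  n_mito <- round(totals * mito_frac)
  n_prom <- round(totals * prom_frac)
  n_bg <- pmax(totals - n_peak - n_mito - n_prom, 0)

  ## mitochondrial fragments
  mlen <- layout$length[[layout$mito]]
  mi <- rep(seq_len(n), n_mito)
  ml <- sample(60:150, length(mi), replace = TRUE)
  ms <- floor(stats::runif(length(mi), 0, mlen - ml))
  mito_frags <- data.table::data.table(chrom = layout$mito, start = ms,
                                       end = ms + ml,
                                       barcode = cells$barcode[mi])

  ## promoter fragments, gene choice weighted toward own-type markers
  gm <- truth$genes
  fc <- 2^cfg$marker_log2_fold_change
  gene_w <- matrix(1, length(truth$cell_types), nrow(gm$genes),
                   dimnames = list(truth$cell_types, gm$genes$gene_id))
  for (t in truth$cell_types)
    gene_w[t, truth$markers$gene_id[truth$markers$cell_type == t]] <- fc
  pi_list <- vector("list", length(truth$cell_types))
  for (k in seq_along(truth$cell_types)) {
    t <- truth$cell_types[k]
    rows <- which(cells$cell_type == t)
    tot <- sum(n_prom[rows])
    gidx <- sample.int(nrow(gm$genes), tot, replace = TRUE, prob = gene_w[t, ])
    pi_list[[k]] <- data.table::data.table(
      cell = rep(rows, n_prom[rows]), gene = gidx)
  }
  pr <- data.table::rbindlist(pi_list)
  prl <- sample(60:150, nrow(pr), replace = TRUE)
  tss <- gm$genes$tss[pr$gene]
  prs <- floor(stats::runif(nrow(pr), pmax(tss - 2000, 0), tss + 2000 - prl))
  prom_frags <- data.table::data.table(
    chrom = gm$genes$chrom[pr$gene], start = prs, end = prs + prl,
    barcode = cells$barcode[pr$cell])

  ## background fragments, uniform outside peaks (rejection sampling)
  autos <- sim_autosomes(layout)
  alens <- layout$length[autos]
  bi <- rep(seq_len(n), n_bg)
  m <- length(bi)
  bch <- sample(autos, m, replace = TRUE, prob = alens / sum(alens))
  bl <- sample(60:150, m, replace = TRUE)
  bs <- floor(stats::runif(m, 0, alens[bch] - bl))
  peak_gr <- intervals_to_granges(truth_peak_intervals(truth))
  repeat {
    bad <- GenomicRanges::countOverlaps(
      intervals_to_granges(data.frame(chrom = bch, start = bs, end = bs + bl)),
      peak_gr) > 0
    if (!any(bad)) break
    k <- sum(bad)
    bch[bad] <- sample(autos, k, replace = TRUE, prob = alens / sum(alens))
    bl[bad] <- sample(60:150, k, replace = TRUE)
    bs[bad] <- floor(stats::runif(k, 0, alens[bch[bad]] - bl[bad]))
  }
  bg_frags <- data.table::data.table(chrom = bch, start = bs, end = bs + bl,
                                     barcode = cells$barcode[bi])

  frags <- data.table::rbindlist(list(peak_frags, mito_frags, prom_frags,
                                      bg_frags))
  frags <- unique(frags, by = c("chrom", "start", "end", "barcode"))
  frags[, chrom := factor(chrom, levels = layout$chrom)]
  data.table::setorder(frags, chrom, start, end, barcode)
  frags[, chrom := as.character(chrom)]
  frags[, count := 1L]
  list(fragments = as.data.frame(frags), truth = truth)
}

#' Simulate RNA counts coupled to the planted ATAC structure
#'
#' Negative-binomial counts over the truth's gene universe for the QC-passing
#' cells (RNA and ATAC share barcodes 1:1 by default; pass
#' `paired = FALSE` for modality-private barcodes). Planted marker genes have
#' their mean multiplied by `2^marker_log2_fold_change` in their own type;
#' each marker is coupled to a same-type planted peak within the CRE window of
#' its TSS (see [build_truth()]).
#'
#' @param config A [sim_config()].
#' @param truth A [build_truth()] result.
#' @param paired Keep ATAC barcodes (default) or generate RNA-private ones.
#' @return Integer matrix, cells x genes.
#' @export
simulate_rna_counts <- function(config, truth, paired = TRUE) {
  cfg <- truth$config
  set.seed(cfg$seed + 3L)
  cdf <- truth$cells[truth$cells$qc_violation == "none", ]
  mu <- matrix(cfg$rna_nb_mean, nrow(cdf), nrow(truth$genes$genes),
               dimnames = list(cdf$barcode, truth$genes$genes$gene_id))
  fc <- 2^cfg$marker_log2_fold_change
  for (t in truth$cell_types) {
    mk <- truth$markers$gene_id[truth$markers$cell_type == t]
    mu[cdf$cell_type == t, mk] <- mu[cdf$cell_type == t, mk] * fc
  }
  sf <- stats::rlnorm(nrow(cdf), 0, 0.2)
  mu <- mu * sf
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = cfg$rna_nb_dispersion),
                   nrow(mu), ncol(mu), dimnames = dimnames(mu))
  if (!paired) rownames(counts) <- sprintf("RNA%05d", seq_len(nrow(counts)))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a gene-activity modality coupled to the planted markers
#'
#' Poisson gene-level accessibility scores with the same planted elevation as
#' the RNA markers, for cross-modality concordance experiments at gene level
#' without rebuilding activity from fragments.
#'
#' @inheritParams simulate_rna_counts
#' @return Integer matrix, cells x genes.
#' @export
simulate_gene_activity <- function(config, truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 7L)
  cdf <- truth$cells[truth$cells$qc_violation == "none", ]
  lam <- matrix(cfg$activity_mean, nrow(cdf), nrow(truth$genes$genes),
                dimnames = list(cdf$barcode, truth$genes$genes$gene_id))
  fc <- 2^cfg$marker_log2_fold_change
  for (t in truth$cell_types) {
    mk <- truth$markers$gene_id[truth$markers$cell_type == t]
    lam[cdf$cell_type == t, mk] <- lam[cdf$cell_type == t, mk] * fc
  }
  lam <- lam * stats::rlnorm(nrow(cdf), 0, 0.2)
  counts <- matrix(stats::rpois(length(lam), lam), nrow(lam), ncol(lam),
                   dimnames = dimnames(lam))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a branching developmental trajectory
#'
#' Assigns cells to lineages (root-to-leaf paths of the stage graph) with
#' uniform pseudotime; a cell's stage is the pseudotime quantile bin along its
#' lineage path, so pseudotime is non-decreasing along every ancestry path.
#' For each graph edge, `n_transition_peaks_per_edge` null peaks are planted
#' as transition events: half switch p0 -> p1 in the descendant subtree
#' (opening), half p1 -> p0 (closing).
#'
#' @param config A [sim_config()].
#' @param truth A [build_truth()] result.
#' @return List with `cells` (barcode, lineage, pseudotime, stage) and
#'   `transitions` (from, to, peak, direction).
#' @export
simulate_trajectory <- function(config, truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 4L)
  graph <- cfg$stage_graph
  paths <- cfg$lineage_paths
  bad <- setdiff(unlist(paths), graph$stages)
  if (length(bad)) stop("lineage paths mention unknown stages: ",
                        paste(bad, collapse = ", "))
  rows <- list()
  bc <- 0
  for (l in names(paths)) {
    path <- paths[[l]]
    L <- length(path)
    nc <- cfg$cells_per_stage * L
    u <- stats::runif(nc)
    stage <- path[pmin(floor(u * L) + 1L, L)]
    rows[[l]] <- data.frame(
      barcode = sprintf("TJ%06d", bc + seq_len(nc)), lineage = l,
      pseudotime = u, stage = stage, stringsAsFactors = FALSE)
    bc <- bc + nc
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL

  edges <- graph$edges
  npe <- cfg$n_transition_peaks_per_edge
  pool <- truth$peaks$name[is.na(truth$peaks$specific_type)]
  need <- nrow(edges) * npe
  if (length(pool) < need)
    stop("not enough null peaks to plant transition events")
  chosen <- sample(pool, need)
  transitions <- data.frame(
    from = rep(edges$from, each = npe), to = rep(edges$to, each = npe),
    peak = chosen,
    direction = rep(rep_len(c("opened", "closed"), npe), nrow(edges)),
    stringsAsFactors = FALSE)
  list(cells = cells, transitions = transitions)
}

#' Simulate the stage-trajectory cell-by-peak matrix
#'
#' Bernoulli accessibility for trajectory cells: baseline `p0` everywhere,
#' with each planted transition peak at `p1` inside (opening) or outside
#' (closing) the subtree below its edge's descendant stage.
#'
#' @param config A [sim_config()].
#' @param truth A [build_truth()] result.
#' @param trajectory A [simulate_trajectory()] result.
#' @return Sparse binary dgCMatrix, trajectory cells x peaks.
#' @export
simulate_stage_peak_matrix <- function(config, truth, trajectory) {
  cfg <- truth$config
  set.seed(cfg$seed + 5L)
  graph <- cfg$stage_graph
  cells <- trajectory$cells
  p <- matrix(cfg$p0, nrow(cells), nrow(truth$peaks),
              dimnames = list(cells$barcode, truth$peaks$name))
  tr <- trajectory$transitions
  for (i in seq_len(nrow(tr))) {
    inside <- cells$stage %in% stage_descendants(graph, tr$to[i])
    j <- match(tr$peak[i], truth$peaks$name)
    p[, j] <- ifelse(if (tr$direction[i] == "opened") inside else !inside,
                     cfg$p1, cfg$p0)
  }
  x <- matrix(stats::rbinom(length(p), 1L, p), nrow(p), ncol(p),
              dimnames = dimnames(p))
  methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
}

#' Simulate GWAS SNPs around the planted peaks
#'
#' A configured fraction of SNPs is placed uniformly inside planted
#' cell-type-specific peaks; the remainder uniformly outside all peaks.
#' Placement is recorded so in-peak recovery can be checked exactly.
#'
#' @param config A [sim_config()].
#' @param truth A [build_truth()] result.
#' @return List with `snps` (BED-style single-base intervals) and `placement`
#'   (snp, in_peak, peak, cell_type).
#' @export
simulate_gwas_snps <- function(config, truth) {
  cfg <- truth$config
  set.seed(cfg$seed + 6L)
  n_in <- round(cfg$snp_in_peak_fraction * cfg$n_snps)
  n_out <- cfg$n_snps - n_in
  spec <- truth$peaks[!is.na(truth$peaks$specific_type), ]
  pk <- spec[sample.int(nrow(spec), n_in, replace = TRUE), ]
  pos_in <- floor(stats::runif(n_in, pk$start, pk$end))
  layout <- truth$layout
  autos <- sim_autosomes(layout)
  alens <- layout$length[autos]
  ch <- sample(autos, n_out, replace = TRUE, prob = alens / sum(alens))
  pos <- floor(stats::runif(n_out, 0, alens[ch]))
  peak_gr <- intervals_to_granges(truth_peak_intervals(truth))
  repeat {
    bad <- GenomicRanges::countOverlaps(
      intervals_to_granges(data.frame(chrom = ch, start = pos, end = pos + 1)),
      peak_gr) > 0
    if (!any(bad)) break
    k <- sum(bad)
    ch[bad] <- sample(autos, k, replace = TRUE, prob = alens / sum(alens))
    pos[bad] <- floor(stats::runif(k, 0, alens[ch[bad]]))
  }
  snps <- data.frame(
    chrom = c(pk$chrom, ch), start = c(pos_in, pos),
    end = c(pos_in, pos) + 1,
    name = sprintf("rs%05d", seq_len(cfg$n_snps)), stringsAsFactors = FALSE)
  placement <- data.frame(
    snp = snps$name, in_peak = c(rep(TRUE, n_in), rep(FALSE, n_out)),
    peak = c(pk$name, rep(NA_character_, n_out)),
    cell_type = c(pk$specific_type, rep(NA_character_, n_out)),
    stringsAsFactors = FALSE)
  o <- order(match(snps$chrom, layout$chrom), snps$start)
  list(snps = snps[o, ], placement = placement[o, ])
}

#' Write fragment records as a 10x-style fragments file
#'
#' Tab-separated chrom, start, end, barcode, count without header; gzipped
#' when `path` ends in `.gz`.
#'
#' @param fragments data.frame with those five columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end", "barcode") %in% names(fragments)))
  if (is.null(fragments$count)) fragments$count <- 1L
  data.table::fwrite(
    fragments[, c("chrom", "start", "end", "barcode", "count")], path,
    sep = "\t", col.names = FALSE, quote = FALSE, scipen = 50,
    compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Read a fragments file
#'
#' @param path Plain or gzipped TSV with columns chrom, start, end, barcode
#'   and optionally count.
#' @return data.frame of fragment records.
#' @export
read_fragments <- function(path) {
  df <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(df) < 4) stop("fragments file must have >= 4 columns")
  names(df)[1:4] <- c("chrom", "start", "end", "barcode")
  if (ncol(df) >= 5) names(df)[5] <- "count" else df$count <- 1L
  df$chrom <- as.character(df$chrom)
  df$barcode <- as.character(df$barcode)
  df[, c("chrom", "start", "end", "barcode", "count")]
}

#' Serialize a synthetic truth bundle to plain-text tables
#'
#' Writes cells, markers, peaks, cis couples, blacklist and gene models (and,
#' if supplied, trajectory and SNP placement truth) as TSV/BED files under
#' `dir`.
#'
#' @param truth A [build_truth()] result.
#' @param dir Output directory (created if needed).
#' @param trajectory Optional [simulate_trajectory()] result.
#' @param snps Optional [simulate_gwas_snps()] result.
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(truth, dir, trajectory = NULL, snps = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, scipen = 50)
  wt(truth$cells, "truth_cells.tsv")
  wt(truth$markers, "truth_markers.tsv")
  wt(truth$peaks, "truth_peaks.tsv")
  wt(truth$links, "truth_links.tsv")
  write_bed(truth$blacklist, file.path(dir, "blacklist.bed"))
  write_bed(truth_peak_intervals(truth), file.path(dir, "peaks.bed"))
  write_gene_models_tab(truth$genes, file.path(dir, "gene_models.tsv"))
  if (!is.null(trajectory)) {
    wt(trajectory$cells, "truth_trajectory_cells.tsv")
    wt(trajectory$transitions, "truth_transitions.tsv")
  }
  if (!is.null(snps)) {
    write_bed(snps$snps, file.path(dir, "snps.bed"))
    wt(snps$placement, "truth_snp_placement.tsv")
  }
  invisible(dir)
}
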