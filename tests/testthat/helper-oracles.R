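# Independent oracles used across the suite. Each is a deliberately naive
# implementation (enumeration, brute-force scan, literal definition) kept
# separate from the package's own code paths.

# Upper hypergeometric tail P(X >= a) by direct summation of choose() terms.
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c          # accessible cells overall
  n <- a + b          # focal group size
  ks <- a:min(K, n)
  if (length(ks) == 0 || a > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Literal BH step-up definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided rank-sum p by full enumeration of all C(m+n, m) group
# assignments (tie-free data only).
oracle_wilcox_two_sided <- function(x, y) {
  v <- c(x, y)
  stopifnot(!any(duplicated(v)))
  m <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(m)])
  combs <- utils::combn(length(v), m)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- m * (length(v) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Integer coverage array of an interval set (coordinates < 1e5).
oracle_coverage <- function(df, len = 1e5) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    v <- logical(len)
    sub <- df[df$chrom == ch, ]
    for (i in seq_len(nrow(sub)))
      v[(sub$start[i] + 1):sub$end[i]] <- TRUE
    out[[ch]] <- v
  }
  out
}

# Exhaustive nearest-anchor scan for a single point.
oracle_nearest <- function(chrom, pos, features) {
  fs <- features[features$chrom == chrom, , drop = FALSE]
  if (nrow(fs) == 0) return(NULL)
  d <- abs(pos - fs$anchor)
  best <- which(d == min(d))
  best <- best[order(fs$start[best], fs$name[best])][1]
  list(name = fs$name[best], dist = d[best])
}

# A tiny two-chromosome genome for interval unit tests.
tiny_layout <- function() {
  genome_layout(chrom = c("chr1", "chr2", "chrM"),
                length = c(100000, 50000, 16000), mito = "chrM",
                sex = character())
}

# A hand-crafted two-gene model set (one per strand) on chr1.
tiny_genes <- function() {
  gene_models(
    genes = data.frame(
      gene_id = c("gA", "gB"), chrom = "chr1", strand = c("+", "-"),
      start = c(10000, 40000), end = c(20000, 48000)),
    exons = data.frame(gene_id = c("gA", "gA", "gB"),
                       start = c(10000, 18000, 46000),
                       end = c(11000, 20000, 48000)),
    utr5 = data.frame(gene_id = c("gA", "gB"),
                      start = c(10000, 47800), end = c(10200, 48000)),
    utr3 = data.frame(gene_id = c("gA", "gB"),
                      start = c(19800, 46000), end = c(20000, 46200)))
}

# Small simulation config for fast tests; ... overrides any default.
small_sim <- function(seed = 1L, ...) {
  args <- list(n_cell_types = 3, n_cells_per_type = 60, n_peaks = 200,
               n_specific_peaks_per_type = 15, n_genes = 120,
               n_marker_genes_per_type = 5, cells_per_stage = 40,
               n_snps = 60, n_blacklist = 2, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Brute-force all-pairs application of the three CRE linking predicates.
oracle_links <- function(pk, dg, genes, window) {
  out <- list()
  for (i in seq_len(nrow(dg))) for (j in seq_len(nrow(pk))) {
    g <- genes$genes[genes$genes$gene_id == dg$gene[i], ]
    if (dg$group[i] != pk$cell_type[j]) next
    if (g$chrom != pk$chrom[j]) next
    tss <- g$tss
    if (pk$start[j] <= tss && tss < pk$end[j]) next
    gap <- if (tss >= pk$end[j]) tss - pk$end[j] else pk$start[j] - tss
    if (gap > window) next
    out[[length(out) + 1]] <- paste(dg$gene[i], pk$peak[j], dg$group[i])
  }
  if (length(out) == 0) return(character(0))
  sort(unlist(out))
}
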