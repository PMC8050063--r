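test_that("fragment simulation is byte-deterministic under a fixed seed", {
  cfg <- small_sim(seed = 3L)
  f1 <- simulate_atac_fragments(cfg)
  f2 <- simulate_atac_fragments(cfg)
  expect_identical(f1$fragments, f2$fragments)
  p1 <- tempfile(); p2 <- tempfile()
  write_fragments(f1$fragments, p1)
  write_fragments(f2$fragments, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
})

test_that("planted accessibility rates are realized at fragment level", {
  # 200 target-type cells at p1 = 0.8: the per-cell fraction with >= 1
  # fragment in a planted peak must fall in the exact binomial 99% interval.
  cfg <- sim_config(n_cell_types = 2, n_cells_per_type = 200, n_peaks = 100,
                    n_specific_peaks_per_type = 10, p1 = 0.8, n_genes = 60,
                    n_marker_genes_per_type = 4, n_snps = 20, seed = 5L)
  fr <- simulate_atac_fragments(cfg)
  truth <- fr$truth
  m <- build_cell_peak_matrix(fr$fragments, truth_peak_intervals(truth),
                              barcodes = truth$cells$barcode)
  t1 <- truth$cells$barcode[truth$cells$cell_type == "T1" &
                              truth$cells$qc_violation == "none"]
  planted1 <- truth$peaks$name[!is.na(truth$peaks$specific_type) &
                                 truth$peaks$specific_type == "T1"]
  frac <- sum(m[t1, planted1]) / (length(t1) * length(planted1))
  n_draws <- length(t1) * length(planted1)
  lo <- qbinom(0.005, n_draws, 0.8) / n_draws
  hi <- qbinom(0.995, n_draws, 0.8) / n_draws
  expect_gte(frac, lo)
  expect_lte(frac, hi)
})

test_that("truth bookkeeping matches the configured design", {
  cfg <- small_sim(seed = 2L)
  truth <- build_truth(cfg)
  planted <- truth$peaks[!is.na(truth$peaks$specific_type), ]
  expect_equal(nrow(planted),
               cfg$n_cell_types * cfg$n_specific_peaks_per_type)
  expect_equal(unname(table(planted$specific_type)),
               rep(cfg$n_specific_peaks_per_type, cfg$n_cell_types),
               ignore_attr = TRUE)
  # every planted peak belongs to exactly one type by construction
  expect_false(any(duplicated(planted$name)))
  # peaks disjoint with >= 1 gap
  o <- order(truth$peaks$chrom, truth$peaks$start)
  pk <- truth$peaks[o, ]
  same <- pk$chrom[-nrow(pk)] == pk$chrom[-1]
  expect_true(all(!same | pk$start[-1] > pk$end[-nrow(pk)]))
  # marker-coupled peaks lie within the CRE window, off the TSS
  tss <- truth$genes$genes$tss[match(truth$links$gene_id,
                                     truth$genes$genes$gene_id)]
  pk <- truth$peaks[match(truth$links$peak, truth$peaks$name), ]
  expect_true(all(truth$links$distance <= cfg$cre_window))
  expect_true(all(tss < pk$start | tss >= pk$end))
})

test_that("RNA counts are reproducible non-negative integers with the planted fold change", {
  lfc <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_cell_types = 2, n_cells_per_type = 200, n_peaks = 60,
                      n_specific_peaks_per_type = 6, n_genes = 80,
                      n_marker_genes_per_type = 4, n_snps = 10, seed = 300L + s)
    truth <- build_truth(cfg)
    rna <- simulate_rna_counts(cfg, truth)
    if (s == 1) {
      expect_true(all(rna >= 0))
      expect_true(is.integer(rna))
      expect_identical(rna, simulate_rna_counts(cfg, truth))
    }
    g <- truth$markers$gene_id[truth$markers$cell_type == "T1"][1]
    clean <- truth$cells[truth$cells$qc_violation == "none", ]
    own <- rownames(rna) %in% clean$barcode[clean$cell_type == "T1"]
    lfc <- c(lfc, log2(mean(rna[own, g]) / mean(rna[!own, g])))
  }
  expect_lt(abs(mean(lfc) - 2), 0.2)
})

test_that("trajectory stages respect the graph and the planted event split", {
  cfg <- small_sim(seed = 4L)
  truth <- build_truth(cfg)
  traj <- simulate_trajectory(cfg, truth)
  g <- cfg$stage_graph
  # every stage reachable from the root
  expect_true(all(traj$cells$stage %in% stage_descendants(g, g$root)))
  # expected pseudotime increases stage by stage along each lineage path
  for (l in names(cfg$lineage_paths)) {
    path <- cfg$lineage_paths[[l]]
    sub <- traj$cells[traj$cells$lineage == l, ]
    mt <- tapply(sub$pseudotime, factor(sub$stage, levels = path), mean)
    expect_true(all(diff(mt) > 0))
  }
  # opened:closed split per edge
  tab <- table(paste(traj$transitions$from, traj$transitions$to),
               traj$transitions$direction)
  expect_true(all(tab[, "opened"] == ceiling(cfg$n_transition_peaks_per_edge / 2)))
  expect_true(all(tab[, "closed"] == floor(cfg$n_transition_peaks_per_edge / 2)))
})

test_that("SNPs land where the truth says they land", {
  cfg <- small_sim(seed = 6L)
  truth <- build_truth(cfg)
  sn <- simulate_gwas_snps(cfg, truth)
  expect_true(all(sn$snps$start >= 0))
  expect_true(all(sn$snps$end <= truth$layout$length[sn$snps$chrom]))
  expect_equal(mean(sn$placement$in_peak), cfg$snp_in_peak_fraction)
  # brute-force half-open interval scan agrees with the recorded placement
  pk <- truth$peaks
  in_pk <- vapply(seq_len(nrow(sn$snps)), function(i)
    any(pk$chrom == sn$snps$chrom[i] & pk$start <= sn$snps$start[i] &
          sn$snps$start[i] < pk$end), logical(1))
  expect_identical(in_pk, sn$placement$in_peak)
})

test_that("truth bundles serialize to plain-text files", {
  cfg <- small_sim(seed = 8L)
  truth <- build_truth(cfg)
  d <- tempfile()
  write_truth_bundle(truth, d, trajectory = simulate_trajectory(cfg, truth),
                     snps = simulate_gwas_snps(cfg, truth))
  expect_true(all(file.exists(file.path(d, c(
    "truth_cells.tsv", "truth_markers.tsv", "truth_peaks.tsv",
    "truth_links.tsv", "blacklist.bed", "peaks.bed", "gene_models.tsv",
    "truth_transitions.tsv", "snps.bed")))))
  gm <- read_gene_models_tab(file.path(d, "gene_models.tsv"))
  expect_equal(gm$genes, truth$genes$genes, ignore_attr = TRUE)
})
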