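test_that("the three linking predicates are applied literally", {
  genes <- gene_models(genes = data.frame(
    gene_id = "podogene", chrom = "chr1", strand = "+",
    start = 1e6, end = 1e6 + 2e4))
  mk_peak <- function(start, end, type = "Podo", name = "pk")
    data.frame(peak = name, cell_type = type, chrom = "chr1",
               start = start, end = end)
  degs <- data.frame(gene = "podogene", group = "Podo", significant = TRUE)
  # 50 kb away, same type -> linked
  l1 <- link_daps_to_degs(mk_peak(1e6 + 5e4, 1e6 + 5e4 + 400), degs, genes)
  expect_equal(nrow(l1), 1)
  expect_equal(l1$distance, 5e4)         # nearer-edge convention
  # 150 kb away -> not linked
  expect_equal(nrow(link_daps_to_degs(
    mk_peak(1e6 + 1.5e5, 1e6 + 1.5e5 + 400), degs, genes)), 0)
  # nearer edge decides: far edge beyond the window still links...
  edge_in <- mk_peak(1e6 + 1e5 - 1, 1e6 + 1e5 + 399)
  expect_equal(nrow(link_daps_to_degs(edge_in, degs, genes)), 1)
  # ...while a nearer edge one base past the window does not
  edge_out <- mk_peak(1e6 + 1e5 + 1, 1e6 + 1e5 + 401)
  expect_equal(nrow(link_daps_to_degs(edge_out, degs, genes)), 0)
  # peak containing the TSS -> never linked
  expect_equal(nrow(link_daps_to_degs(
    mk_peak(1e6 - 100, 1e6 + 100), degs, genes)), 0)
  # abutting peak: distance 0, linked
  l0 <- link_daps_to_degs(mk_peak(1e6 - 400, 1e6), degs, genes)
  expect_equal(l0$distance, 0)
  # wrong cell type -> not linked
  expect_equal(nrow(link_daps_to_degs(
    mk_peak(1e6 + 5e4, 1e6 + 5e4 + 400, type = "PT"), degs, genes)), 0)
  # missing gene models -> error naming the gene
  expect_error(link_daps_to_degs(
    mk_peak(1e6, 1e6 + 400),
    data.frame(gene = "ghost", group = "Podo", significant = TRUE), genes),
    "ghost")
})

test_that("upstream links carry negative distances in the gene's orientation", {
  genes <- gene_models(genes = data.frame(
    gene_id = c("plus", "minus"), chrom = "chr1", strand = c("+", "-"),
    start = c(1e6, 2e6), end = c(1e6 + 1e4, 2e6 + 1e4)))
  degs <- data.frame(gene = c("plus", "minus"), group = "T1",
                     significant = TRUE)
  pk <- data.frame(peak = c("left_of_plus", "right_of_minus"),
                   cell_type = "T1", chrom = "chr1",
                   start = c(1e6 - 5e4, 2e6 + 3e4),
                   end = c(1e6 - 5e4 + 400, 2e6 + 3e4 + 400))
  l <- link_daps_to_degs(pk, degs, genes)
  expect_lt(l$distance[l$peak == "left_of_plus"], 0)
  expect_lt(l$distance[l$peak == "right_of_minus"], 0)   # - strand upstream
})

test_that("link output equals the brute-force predicate scan on random fixtures", {
  set.seed(83)
  for (rep in 1:20) {
    ng <- sample(3:8, 1); np <- sample(3:12, 1)
    genes <- gene_models(genes = data.frame(
      gene_id = sprintf("g%02d", seq_len(ng)),
      chrom = sample(c("chr1", "chr2"), ng, TRUE),
      strand = sample(c("+", "-"), ng, TRUE),
      start = st <- sample(seq(2e5, 2e6, 1e4), ng), end = st + 5000))
    pk <- data.frame(peak = sprintf("p%02d", seq_len(np)),
                     cell_type = sample(c("A", "B"), np, TRUE),
                     chrom = sample(c("chr1", "chr2"), np, TRUE),
                     start = ps <- sample(seq(1e5, 2.1e6, 997), np))
    pk$end <- pk$start + 400
    dg <- data.frame(gene = genes$genes$gene_id,
                     group = sample(c("A", "B"), ng, TRUE),
                     significant = sample(c(TRUE, FALSE), ng, TRUE, c(.8, .2)))
    got <- link_daps_to_degs(pk, dg, genes, window = 1e5)
    want <- oracle_links(pk, dg[dg$significant, ], genes, 1e5)
    expect_identical(sort(paste(got$gene, got$peak, got$cell_type)), want)
    # every emitted link satisfies all three predicates
    if (nrow(got)) {
      tss <- genes$genes$tss[match(got$gene, genes$genes$gene_id)]
      expect_true(all(abs(got$distance) <= 1e5))
      expect_true(all(got$start > tss | got$end <= tss))
    }
  }
})

test_that("planted couples are fully recovered when their DAP and DEG are recovered", {
  cfg <- small_sim(seed = 89L)
  truth <- build_truth(cfg)
  pm <- simulate_peak_matrix(cfg, truth)
  dap <- call_cell_type_specific_peaks(pm$matrix, pm$labels,
                                       peaks = truth$peaks)
  rna <- simulate_rna_counts(cfg, truth)
  clean <- truth$cells[truth$cells$qc_violation == "none", ]
  degs <- wilcoxon_de_all(normalize_rpm_log(rna),
                          setNames(clean$cell_type, clean$barcode))
  links <- link_daps_to_degs(dap, degs, truth$genes,
                             window = cfg$cre_window)
  got <- paste(links$gene, links$peak, links$cell_type)
  dap_ok <- paste(dap$calls$peak, dap$calls$cell_type)
  deg_ok <- paste(degs$gene[degs$significant], degs$group[degs$significant])
  tr <- truth$links
  recovered_parents <- paste(tr$peak, tr$cell_type) %in% dap_ok &
    paste(tr$gene_id, tr$cell_type) %in% deg_ok
  expect_gt(sum(recovered_parents), 0)
  expect_true(all(paste(tr$gene_id, tr$peak, tr$cell_type)[recovered_parents]
                  %in% got))
})
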