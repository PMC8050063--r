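test_that("RPM-log normalization follows the closed form and is scale-invariant", {
  counts <- matrix(c(10, 999990, 0, 5), 2, 2, byrow = TRUE,
                   dimnames = list(c("c1", "c2"), c("g1", "g2")))
  norm <- normalize_rpm_log(counts)
  expect_equal(norm["c1", "g1"], log(1 + 10), tolerance = 1e-12)
  expect_equal(norm["c2", "g1"], 0)
  doubled <- counts; doubled["c1", ] <- doubled["c1", ] * 2
  expect_equal(normalize_rpm_log(doubled)["c1", ], norm["c1", ],
               tolerance = 1e-12)
  bad <- rbind(counts, dead = c(0, 0))
  expect_error(normalize_rpm_log(bad), "dead")
})

test_that("rank-sum p-values match full enumeration on small tie-free samples", {
  norm <- rbind(matrix(c(1, 2, 3), 3, 1), matrix(c(4, 5, 6), 3, 1))
  dimnames(norm) <- list(sprintf("c%d", 1:6), "g1")
  groups <- setNames(rep(c("A", "B"), each = 3), rownames(norm))
  de <- wilcoxon_de(norm, groups, "A", min_pct = 0, min_logfc = 0)
  expect_equal(de$p, 0.1, tolerance = 1e-12)
  expect_equal(de$p, oracle_wilcox_two_sided(1:3, 4:6), tolerance = 1e-12)
  set.seed(23)
  for (rep in 1:15) {
    m <- sample(2:6, 1); n <- sample(2:6, 1)
    v <- sample(1:1000, m + n) / 100
    x <- v[seq_len(m)]; y <- v[-seq_len(m)]
    norm <- matrix(c(x, y), ncol = 1,
                   dimnames = list(sprintf("c%d", seq_len(m + n)), "g"))
    groups <- setNames(rep(c("A", "B"), c(m, n)), rownames(norm))
    de <- wilcoxon_de(norm, groups, "A", min_pct = 0, min_logfc = 0)
    expect_equal(de$p, oracle_wilcox_two_sided(x, y), tolerance = 1e-12)
  }
})

test_that("the large-sample approximation stays close to the exact distribution", {
  # at m = n = 20 the package takes the normal-approximation path; compare
  # against the exact tie-free distribution
  set.seed(29)
  for (rep in 1:10) {
    v <- sample(1:10000, 40) / 1000
    x <- v[1:20]; y <- v[21:40]
    norm <- matrix(c(x, y), ncol = 1,
                   dimnames = list(sprintf("c%d", 1:40), "g"))
    groups <- setNames(rep(c("A", "B"), each = 20), rownames(norm))
    de <- wilcoxon_de(norm, groups, "A", min_pct = 0, min_logfc = 0)
    exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(de$p - exact), 0.01)
  }
})

test_that("DE prefilters exclude undetected and flat genes before testing", {
  set.seed(37)
  n <- 40
  norm <- cbind(
    rare = c(rep(1, 2), rep(0, 18), rep(1, 2), rep(0, 18)),   # 10% both groups
    flat = rep(c(1.00, 1.01), n / 2),                          # logFC ~ 0
    real = c(rnorm(20, 5, 0.1), rnorm(20, 1, 0.1)))
  rownames(norm) <- sprintf("c%d", seq_len(n))
  groups <- setNames(rep(c("A", "B"), each = 20), rownames(norm))
  de <- wilcoxon_de(norm, groups, "A")
  expect_false("rare" %in% de$gene)
  expect_false("flat" %in% de$gene)
  expect_true("real" %in% de$gene)
  expect_true(de$significant[de$gene == "real"])
  # identical distributions are never significant
  same <- cbind(g = rep(c(0, 3), n / 2))
  rownames(same) <- rownames(norm)
  de2 <- wilcoxon_de(same, groups, "A", min_pct = 0, min_logfc = 0)
  expect_false(any(de2$significant))
  expect_error(wilcoxon_de(norm, groups, "Z"), "focal")
})

test_that("DE significance equals applying bh_adjust to the raw p-values", {
  cfg <- small_sim(seed = 41L)
  truth <- build_truth(cfg)
  rna <- simulate_rna_counts(cfg, truth)
  norm <- normalize_rpm_log(rna)
  clean <- truth$cells[truth$cells$qc_violation == "none", ]
  labels <- setNames(clean$cell_type, clean$barcode)
  de <- wilcoxon_de(norm, labels, "T1")
  expect_equal(de$p_adj, bh_adjust(de$p), tolerance = 1e-12)
  expect_identical(de$significant, de$p_adj < 0.05)
  expect_true(all(de$p_adj >= de$p - 1e-15))
})

test_that("planted markers are recovered with high sensitivity and controlled FDR", {
  tp <- 0; fp <- 0; n_planted <- 0
  for (s in 1:3) {
    cfg <- sim_config(seed = 50L + s)
    truth <- build_truth(cfg)
    rna <- simulate_rna_counts(cfg, truth)
    norm <- normalize_rpm_log(rna)
    clean <- truth$cells[truth$cells$qc_violation == "none", ]
    labels <- setNames(clean$cell_type, clean$barcode)
    de <- wilcoxon_de_all(norm, labels)
    up <- de[de$significant & de$logfc > 0, ]
    key <- paste(truth$markers$gene_id, truth$markers$cell_type)
    hits <- paste(up$gene, up$group)
    tp <- tp + sum(key %in% hits)
    fp <- fp + sum(!hits %in% key)
    n_planted <- n_planted + length(key)
  }
  expect_gte(tp / n_planted, 0.95)
  expect_lte(fp / max(tp + fp, 1), 0.1)
})

test_that("highly variable gene selection ranks planted variance first", {
  set.seed(43)
  m0 <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  expect_setequal(select_hvg(m0, 10), colnames(m0))  # n >= gene count
  hits <- 0
  for (rep in 1:10) {
    base <- matrix(rnorm(200 * 30), 200, 30)
    infl <- sample(30, 5)
    base[, infl] <- base[, infl] * sqrt(10)
    colnames(base) <- sprintf("g%02d", 1:30)
    hits <- hits + sum(sprintf("g%02d", infl) %in% select_hvg(base, 5))
  }
  expect_gte(hits / 50, 0.95)
  # constant genes are never selected while varying genes remain
  m <- cbind(const = rep(1, 10), varying = rnorm(10))
  expect_equal(select_hvg(m, 1), "varying")
})
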