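test_that("cell-bin matrix binarizes, spans bin boundaries, drops chrM", {
  frags <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chrM", "chrUn"),
    start = c(100, 200, 300, 4998, 10, 10),
    end = c(160, 260, 360, 5010, 60, 60),
    barcode = "cellA")
  m <- build_cell_bin_matrix(frags, tiny_layout(), bin_size = 5000)
  expect_true(all(m@x == 1))
  f <- feature_intervals(m)
  expect_equal(unname(m[1, f$start == 0 & f$chrom == "chr1"]), 1)
  expect_equal(unname(m[1, f$start == 5000 & f$chrom == "chr1"]), 1)
  expect_equal(sum(m), 2)                       # chrM/unknown contribute nothing
  expect_false(any(f$chrom == "chrM"))
  m0 <- build_cell_bin_matrix(frags[0, ], tiny_layout(), 5000)
  expect_equal(nrow(m0), 0)
})

test_that("filter_bins removes floor(top_fraction * n) top bins plus blacklist, never rows", {
  set.seed(31)
  n_cells <- 20
  frags <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
    s <- sample(0:99000, 40, TRUE)
    data.frame(chrom = "chr1", start = s, end = s + 50,
               barcode = sprintf("c%02d", i))
  }))
  # a hyper-accessible hotspot in bin [0, 1000)
  hot <- data.frame(chrom = "chr1", start = rep(10, n_cells), end = 60,
                    barcode = sprintf("c%02d", seq_len(n_cells)))
  m <- build_cell_bin_matrix(rbind(frags, hot), tiny_layout(), 1000)
  mf <- filter_bins(m, top_fraction = 0.05)
  expect_equal(nrow(mf), nrow(m))
  expect_equal(ncol(mf), ncol(m) - floor(0.05 * ncol(m)))
  # the removed set equals a full-sort oracle (ties by genomic order)
  cs <- Matrix::colSums(m)
  want_drop <- order(-cs, seq_along(cs))[seq_len(floor(0.05 * ncol(m)))]
  expect_setequal(setdiff(colnames(m), colnames(mf)), colnames(m)[want_drop])
  expect_false("chr1:0-1000" %in% colnames(mf))
  # blacklist removal is unconditional
  mb <- filter_bins(m, top_fraction = 0,
                    blacklist = genomic_intervals("chr1", 2500, 2600))
  expect_false("chr1:2000-3000" %in% colnames(mb))
  expect_equal(ncol(mb), ncol(m) - 1)
})

test_that("cell-peak matrix obeys half-open overlap and matches a brute-force scan", {
  peaks <- genomic_intervals("chr1", c(1000, 3000), c(1500, 3500),
                             name = c("p1", "p2"))
  frags <- data.frame(chrom = "chr1",
                      start = c(900, 500, 1499, 2000),
                      end = c(1000, 2000, 1501, 2500),
                      barcode = c("a", "b", "c", "c"))
  m <- build_cell_peak_matrix(frags, peaks)
  expect_equal(unname(m["a", "p1"]), 0)    # abuts peak start boundary
  expect_equal(unname(m["b", "p1"]), 1)    # contains the whole peak
  expect_equal(unname(m["c", "p1"]), 1)
  expect_equal(sum(m[, "p2"]), 0)
  expect_error(build_cell_peak_matrix(
    frags, genomic_intervals("chr1", c(0, 100), c(200, 300))), "merge")
  set.seed(13)
  pk <- genomic_intervals("chr1", s <- seq(0, 9000, by = 1000) + 100, s + 400,
                          name = sprintf("q%02d", 1:10))
  fr <- data.frame(chrom = "chr1", start = s2 <- sample(0:9500, 300, TRUE),
                   end = s2 + sample(10:200, 300, TRUE),
                   barcode = sample(c("x", "y", "z"), 300, TRUE))
  m2 <- build_cell_peak_matrix(fr, pk)
  for (bc in rownames(m2)) for (j in seq_len(nrow(pk))) {
    sub <- fr[fr$barcode == bc, ]
    want <- as.numeric(any(sub$start < pk$end[j] & pk$start[j] < sub$end))
    expect_equal(unname(m2[bc, j]), want)
  }
})

test_that("gene activity windows follow the scoring mode and strand", {
  gm <- tiny_genes()   # gA: + strand, span [10000,20000); gB: -, [40000,48000)
  up1k <- data.frame(chrom = "chr1", start = 8900, end = 9000,
                     barcode = "c1")  # 1 kb upstream of gA TSS
  m1 <- build_gene_activity_matrix(up1k, gm, mode = "transcript_overlap")
  expect_equal(unname(m1[1, "gA"]), 0)
  m2 <- build_gene_activity_matrix(up1k, gm, mode = "body_plus_upstream")
  expect_equal(unname(m2[1, "gA"]), 1)
  up3k <- data.frame(chrom = "chr1", start = 6900, end = 7000, barcode = "c1")
  m3 <- build_gene_activity_matrix(up3k, gm, mode = "body_plus_upstream")
  expect_equal(unname(m3[1, "gA"]), 0)
  # upstream of a minus-strand gene means higher coordinates
  upB <- data.frame(chrom = "chr1", start = 48500, end = 48600, barcode = "c1")
  m4 <- build_gene_activity_matrix(upB, gm, mode = "body_plus_upstream")
  expect_equal(unname(m4[1, "gB"]), 1)
  # counts accumulate (not binarized)
  two <- rbind(up1k, up1k)
  two$start <- two$start + c(0, 10)
  m5 <- build_gene_activity_matrix(two, gm, mode = "body_plus_upstream")
  expect_equal(unname(m5[1, "gA"]), 2)
})

test_that("pseudobulk profile excludes chrX/Y/M and conserves fragment counts", {
  ly <- genome_layout(c("chr1", "chrX", "chrM"), c(50000, 30000, 16000),
                      mito = "chrM", sex = "chrX")
  set.seed(17)
  fr <- data.frame(chrom = sample(c("chr1", "chrX", "chrM"), 400, TRUE),
                   start = s <- sample(0:15000, 400, TRUE), end = s + 50,
                   barcode = "c1")
  pb <- build_pseudobulk_profile(fr, ly, bin_size = 10000)
  expect_false(any(pb$chrom %in% c("chrX", "chrM")))
  expect_equal(sum(pb$count), sum(fr$chrom == "chr1"))
  # per-bin counts match an exhaustive tally by start position
  for (i in seq_len(nrow(pb)))
    expect_equal(pb$count[i], sum(fr$chrom == pb$chrom[i] &
                                    fr$start >= pb$start[i] &
                                    fr$start < pb$end[i]))
})

test_that("MTX round-trips with barcode and feature sidecars", {
  set.seed(19)
  m <- Matrix::rsparsematrix(8, 5, density = 0.4)
  dimnames(m) <- list(sprintf("bc%d", 1:8), sprintf("ft%d", 1:5))
  pre <- tempfile()
  write_mtx(m, pre)
  m2 <- read_mtx(pre)
  expect_equal(as.matrix(m2), as.matrix(m), tolerance = 1e-12)
  expect_identical(dimnames(m2), dimnames(m))
})
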