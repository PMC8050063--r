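test_that("element priority resolves multi-element overlaps", {
  gm <- tiny_genes()
  # peak over gA's first exon and 5'UTR -> exon wins
  expect_equal(as.character(classify_peak_elements(
    genomic_intervals("chr1", 10050, 10150), gm)), "exon")
  # peak in gA's intron body only
  expect_equal(as.character(classify_peak_elements(
    genomic_intervals("chr1", 12000, 12200), gm)), "intron")
  # no annotation -> distal
  expect_equal(as.character(classify_peak_elements(
    genomic_intervals("chr1", 90000, 90100), gm)), "distal")
  # promoter of + strand gene is upstream of the TSS only
  expect_equal(as.character(classify_peak_elements(
    genomic_intervals("chr1", 6000, 6100), gm)), "promoter")
  # gB promoter lies above its span (- strand)
  expect_equal(as.character(classify_peak_elements(
    genomic_intervals("chr1", 50000, 50100), gm)), "promoter")
})

test_that("intron of one gene outranks promoter of another", {
  gm <- gene_models(
    genes = data.frame(gene_id = c("gI", "gP"), chrom = "chr1",
                       strand = "+", start = c(1000, 16000),
                       end = c(15000, 20000)),
    exons = data.frame(gene_id = c("gI", "gI"), start = c(1000, 14000),
                       end = c(2000, 15000)))
  # region [12000,13000) is gI intron and within gP's 5 kb promoter
  expect_equal(as.character(classify_peak_elements(
    genomic_intervals("chr1", 12000, 12500), gm)), "intron")
})

test_that("all element subsets map to the highest-priority member", {
  # five disjoint single-class regions crafted directly as element sets
  regions <- list(exon = c(1000, 2000), utr5 = c(3000, 4000),
                  utr3 = c(5000, 6000), intron = c(7000, 8000),
                  promoter = c(9000, 10000))
  elements <- lapply(regions, function(r)
    data.frame(chrom = "chr1", start = r[1], end = r[2]))
  classes <- names(regions)
  for (k in 0:5) for (sub in if (k) utils::combn(classes, k,
                                                 simplify = FALSE) else list(character())) {
    if (length(sub) == 0) {
      peak <- genomic_intervals("chr1", 20000, 20100)
      want <- "distal"
    } else {
      # a peak spanning exactly the chosen regions, in an annotation that
      # contains only those element classes
      lo <- min(vapply(sub, function(s) regions[[s]][1], 1))
      hi <- max(vapply(sub, function(s) regions[[s]][2], 1))
      peak <- genomic_intervals("chr1", lo + 50, hi - 50)
      want <- classes[classes %in% sub][1]   # highest-priority member
    }
    got <- classify_by_elements(peak, elements[sub])
    expect_equal(as.character(got), want)
  }
})

test_that("nearest gene annotation is signed by strand and matches a brute-force scan", {
  gm <- gene_models(genes = data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1", strand = "+",
    start = c(100, 300), end = c(250, 500)))
  r <- nearest_gene(data.frame(chrom = "chr1", pos = 150), gm)
  expect_equal(r$gene_id, "g1")
  expect_equal(r$distance, 50)
  expect_equal(nearest_gene(data.frame(chrom = "chr1", pos = 100),
                            gm)$distance, 0)
  expect_false(nearest_gene(data.frame(chrom = "chr7", pos = 5), gm)$hit)
  # upstream of a + gene is negative; of a - gene, positive coordinates flip
  gmm <- gene_models(genes = data.frame(gene_id = "gm", chrom = "chr1",
                                        strand = "-", start = 1000,
                                        end = 2000))
  expect_equal(nearest_gene(data.frame(chrom = "chr1", pos = 2500),
                            gmm)$distance, -501)  # upstream of TSS at 1999
  set.seed(71)
  for (rep in 1:15) {
    n <- sample(3:20, 1)
    genes <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chr1",
                        strand = sample(c("+", "-"), n, TRUE),
                        start = st <- sort(sample(seq(0, 1e5, 100), n)),
                        end = st + 50)
    gm2 <- gene_models(genes)
    pos <- sample(0:1e5, 1)
    got <- nearest_gene(data.frame(chrom = "chr1", pos = pos), gm2)
    fs <- data.frame(chrom = "chr1", start = gm2$genes$tss,
                     name = gm2$genes$gene_id, anchor = gm2$genes$tss)
    fs <- fs[order(fs$anchor, fs$name), ]
    want <- oracle_nearest("chr1", pos, fs)
    expect_equal(abs(got$distance), want$dist)
  }
})

test_that("widening the promoter never demotes a promoter peak to distal", {
  cfg <- small_sim(seed = 73L)
  truth <- build_truth(cfg)
  cls2 <- classify_peak_elements(truth$peaks, truth$genes, 2000)
  cls5 <- classify_peak_elements(truth$peaks, truth$genes, 5000)
  was_prom <- cls2 == "promoter"
  expect_false(any(cls5[was_prom] == "distal"))
})

test_that("SNP-peak overlap equals a brute-force scan and attributes DAP types", {
  peaks <- genomic_intervals("chr1", c(100, 500), c(200, 600),
                             name = c("pA", "pB"))
  daps <- data.frame(peak = "pA", cell_type = "Podo")
  gm <- tiny_genes()
  snps <- genomic_intervals("chr1", c(150, 200, 599, 600, 50), # inside/edge
                            c(151, 201, 600, 601, 51),
                            name = sprintf("rs%d", 1:5))
  ov <- overlap_snps_with_peaks(snps, peaks, daps, gm)
  expect_equal(ov$in_peak, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(ov$cell_types, c("Podo", "", "", "", ""))
  expect_equal(ov$peaks[3], "pB")
  expect_true(all(nzchar(ov$nearest_gene)))
  # brute force over a random fixture
  set.seed(79)
  pk <- genomic_intervals("chr1", s <- seq(100, 9000, by = 500), s + 200,
                          name = sprintf("p%02d", seq_along(s)))
  sn <- genomic_intervals("chr1", q <- sample(0:9500, 100, TRUE), q + 1,
                          name = sprintf("s%03d", 1:100))
  ov2 <- overlap_snps_with_peaks(sn, pk, NULL, gm)
  want <- vapply(seq_len(nrow(sn)), function(i)
    any(pk$start <= sn$start[i] & sn$start[i] < pk$end), logical(1))
  expect_identical(ov2$in_peak, want)
})

test_that("gene model readers enforce structure and convert GTF coordinates", {
  gm <- tiny_genes()
  f <- tempfile(fileext = ".tsv")
  write_gene_models_tab(gm, f)
  gm2 <- read_gene_models_tab(f)
  expect_equal(gm2$genes, gm$genes, ignore_attr = TRUE)
  expect_equal(gm2$exons[order(gm2$exons$gene_id, gm2$exons$start), ],
               gm$exons[order(gm$exons$gene_id, gm$exons$start), ],
               ignore_attr = TRUE)
  expect_error(gene_models(
    genes = data.frame(gene_id = "g", chrom = "c", strand = "+",
                       start = 10, end = 100),
    exons = data.frame(gene_id = "g", start = 5, end = 20)), "span")
  # GTF (1-based inclusive) converts at the boundary
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\ttranscript\t11\t100\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"tX\";"),
    paste0("chr1\tsrc\texon\t11\t40\t.\t+\t.\t",
           "gene_id \"gX\"; transcript_id \"tX\";")), gtf)
  gm3 <- read_gene_models_gtf(gtf)
  expect_equal(gm3$genes$start, 10)
  expect_equal(gm3$genes$end, 100)
  expect_equal(gm3$genes$tss, 10)
  expect_equal(gm3$exons$start, 10)
  expect_equal(gm3$exons$end, 40)
})
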