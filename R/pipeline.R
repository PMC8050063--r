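## End-to-end orchestration: simulate (or load) -> QC -> matrices -> DE ->
## DAP -> stratify -> link -> concordance -> stages -> GWAS, with every
## tabular output written under the run directory and a manifest recording
## parameter snapshot and output digests. Deterministic under the seed:
## re-running an identical config reproduces identical output digests.

#' Pipeline configuration
#'
#' Collects every named constant of the workflow with its study-design
#' default: 5 kb ATAC bins and 10 kb pseudobulk bins, 2 kb QC promoters and
#' 5 kb stratification promoters, DAP/DE significance 0.05, DE prefilters
#' 0.25/0.25, 3000 highly variable genes, 100 kb CRE window, gene activity
#' over gene body + 2 kb upstream.
#'
#' @param out_dir Run output directory.
#' @param input_dir Optional directory of pre-existing inputs (files as
#'   written by [write_truth_bundle()] and [write_fragments()]); when `NULL`
#'   the synthetic study is generated from `sim`.
#' @param sim A [sim_config()] describing the synthetic study.
#' @param thresholds A [qc_thresholds()].
#' @param bin_size_atac,bin_size_pseudobulk Matrix bin widths (bases).
#' @param top_bin_fraction Hyper-accessible bin removal fraction.
#' @param promoter_upstream_qc QC promoter half-width (TSS +/- this).
#' @param promoter_upstream_annotation Stratification promoter upstream width.
#' @param dap_alpha,de_min_pct,de_min_logfc,de_alpha Test thresholds.
#' @param n_hvg Highly-variable-gene count for concordance.
#' @param cre_window CRE linking window (bases).
#' @param activity_mode,activity_upstream Gene-activity scoring window.
#' @param seed Master seed; overrides `sim$seed`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, sim = sim_config(),
                            thresholds = qc_thresholds(),
                            bin_size_atac = 5000, bin_size_pseudobulk = 10000,
                            top_bin_fraction = 0.05,
                            promoter_upstream_qc = 2000,
                            promoter_upstream_annotation = 5000,
                            dap_alpha = 0.05, de_min_pct = 0.25,
                            de_min_logfc = 0.25, de_alpha = 0.05,
                            n_hvg = 3000, cre_window = 100000,
                            activity_mode = "body_plus_upstream",
                            activity_upstream = 2000, seed = 1L) {
  sim$seed <- as.integer(seed)
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  v <- validate_config(cfg)
  if (length(v)) stop("invalid pipeline config:\n  ",
                      paste(v, collapse = "\n  "))
  cfg
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config` (or a bare list with its fields).
#' @return Character vector of violations, each naming the offending field;
#'   empty when the configuration is valid.
#' @export
validate_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  pos <- c("bin_size_atac", "bin_size_pseudobulk", "n_hvg", "cre_window")
  for (f in pos)
    chk(is.numeric(config[[f]]) && config[[f]] > 0,
        paste0(f, ": must be a positive number"))
  for (f in c("dap_alpha", "de_alpha"))
    chk(is.numeric(config[[f]]) && config[[f]] > 0 && config[[f]] < 1,
        paste0(f, ": must lie in (0, 1)"))
  for (f in c("top_bin_fraction", "de_min_pct"))
    chk(is.numeric(config[[f]]) && config[[f]] >= 0 && config[[f]] < 1,
        paste0(f, ": must lie in [0, 1)"))
  chk(is.numeric(config$de_min_logfc) && config$de_min_logfc >= 0,
      "de_min_logfc: must be >= 0")
  for (f in c("promoter_upstream_qc", "promoter_upstream_annotation",
              "activity_upstream"))
    chk(is.numeric(config[[f]]) && config[[f]] >= 0,
        paste0(f, ": must be >= 0"))
  chk(config$activity_mode %in% c("transcript_overlap", "body_plus_upstream"),
      "activity_mode: unknown mode")
  chk(inherits(config$thresholds, "qc_thresholds"),
      "thresholds: must be a qc_thresholds object")
  chk(inherits(config$sim, "sim_config"), "sim: must be a sim_config object")
  if (!is.null(config$input_dir) && !dir.exists(config$input_dir))
    v <- c(v, "input_dir: directory does not exist")
  v
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `sim:` and
#' `thresholds:` sub-maps override [sim_config()] / [qc_thresholds()]
#' defaults field by field.
#'
#' @param path YAML file.
#' @param out_dir Run output directory (overrides any `out_dir` in the file).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$sim %||% list())
  th <- do.call(qc_thresholds, y$thresholds %||% list())
  y$sim <- NULL; y$thresholds <- NULL
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(pipeline_config, c(y, list(sim = sim, thresholds = th)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_pipeline_inputs <- function(config) {
  ind <- config$input_dir
  need <- c("fragments.tsv", "peaks.bed", "gene_models.tsv",
            "truth_cells.tsv", "blacklist.bed")
  missing <- need[!file.exists(file.path(ind, need))]
  if (length(missing))
    stop("missing pipeline input file(s) in ", ind, ": ",
         paste(missing, collapse = ", "))
  list(fragments = read_fragments(file.path(ind, "fragments.tsv")),
       peaks = read_bed(file.path(ind, "peaks.bed")),
       genes = read_gene_models_tab(file.path(ind, "gene_models.tsv")),
       cells = data.table::fread(file.path(ind, "truth_cells.tsv"),
                                 data.table = FALSE),
       blacklist = read_bed(file.path(ind, "blacklist.bed")))
}

#' Run the full workflow
#'
#' Executes simulate (unless `input_dir` is given) -> ATAC/RNA QC -> bin,
#' peak, gene-activity and pseudobulk matrices -> Wilcoxon DE -> all-pairwise
#' Fisher DAP calling -> element stratification -> CRE linking -> modality
#' concordance -> stage-trajectory dynamics -> GWAS SNP mapping, writing all
#' tabular outputs and a JSON manifest under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage log lines.
#' @return The run manifest (named list; also written as `manifest.json`),
#'   with per-stage bookkeeping counts and per-file MD5 digests.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- validate_config(config)
  if (length(v)) stop("invalid pipeline config:\n  ", paste(v, collapse = "\n  "))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  stages <- list()
  files <- character()
  keep_file <- function(...) files <<- c(files, ...)

  ## -- simulate / load ------------------------------------------------------
  sim <- config$sim
  if (is.null(config$input_dir)) {
    say("simulate: building synthetic study (seed ", sim$seed, ")")
    truth <- build_truth(sim)
    fr <- simulate_atac_fragments(sim, truth)
    rna <- simulate_rna_counts(sim, truth)
    traj <- simulate_trajectory(sim, truth)
    snps <- simulate_gwas_snps(sim, truth)
    indir <- file.path(out, "inputs")
    write_truth_bundle(truth, indir, trajectory = traj, snps = snps)
    write_fragments(fr$fragments, file.path(indir, "fragments.tsv"))
    write_mtx(Matrix::Matrix(rna, sparse = TRUE), file.path(indir, "rna"))
    fragments <- fr$fragments
    peaks <- truth_peak_intervals(truth)
    genes <- truth$genes
    cells <- truth$cells
    blacklist <- truth$blacklist
    keep_file(list.files(indir, full.names = TRUE))
  } else {
    say("load: reading inputs from ", config$input_dir)
    inp <- load_pipeline_inputs(config)
    fragments <- inp$fragments; peaks <- inp$peaks; genes <- inp$genes
    cells <- inp$cells; blacklist <- inp$blacklist
    truth <- NULL; rna <- NULL; traj <- NULL; snps <- NULL
  }
  labels_all <- stats::setNames(cells$cell_type, cells$barcode)
  stages$simulate <- list(n_cells = nrow(cells), n_fragments = nrow(fragments),
                          n_peaks = nrow(peaks))

  ## -- qc -------------------------------------------------------------------
  qc_prom <- promoter_windows(genes, upstream = config$promoter_upstream_qc,
                              downstream = config$promoter_upstream_qc)
  qc <- compute_atac_qc(fragments, qc_prom, sim$genome)
  kept <- filter_atac_cells(qc, config$thresholds)
  write_qc_table(qc, config$thresholds, file.path(out, "atac_qc.tsv"))
  keep_file(file.path(out, "atac_qc.tsv"))
  say("qc: kept ", length(kept), "/", nrow(qc), " ATAC cells")
  rna_kept <- NULL
  if (!is.null(rna)) {
    rqc <- compute_rna_qc(rna)
    rna_kept <- filter_rna_cells(rqc, config$thresholds)
    data.table::fwrite(rqc, file.path(out, "rna_qc.tsv"), sep = "\t",
                       quote = FALSE)
    keep_file(file.path(out, "rna_qc.tsv"))
  }
  stages$qc <- list(atac_cells_kept = length(kept),
                    rna_cells_kept = length(rna_kept %||% character()))

  ## -- matrices -------------------------------------------------------------
  fr_kept <- fragments[fragments$barcode %in% kept, , drop = FALSE]
  bin_m <- build_cell_bin_matrix(fr_kept, sim$genome, config$bin_size_atac)
  bin_m <- filter_bins(bin_m, config$top_bin_fraction, blacklist)
  peak_m <- build_cell_peak_matrix(fr_kept, peaks, barcodes = sort(kept))
  act_m <- build_gene_activity_matrix(fr_kept, genes,
                                      mode = config$activity_mode,
                                      upstream = config$activity_upstream,
                                      barcodes = sort(kept))
  pb <- build_pseudobulk_profile(fr_kept, sim$genome,
                                 config$bin_size_pseudobulk)
  write_mtx(peak_m, file.path(out, "cell_peak"))
  data.table::fwrite(as.data.frame(pb), file.path(out, "pseudobulk.tsv"),
                     sep = "\t", quote = FALSE, scipen = 50)
  keep_file(file.path(out, c("cell_peak.mtx", "cell_peak.barcodes.tsv",
                             "cell_peak.features.tsv", "pseudobulk.tsv")))
  say("matrices: ", ncol(bin_m), " bins kept, ", ncol(peak_m), " peaks")
  stages$matrices <- list(bins_kept = ncol(bin_m), peaks = ncol(peak_m))

  ## -- rna de ---------------------------------------------------------------
  degs <- NULL; hvg <- NULL; norm_rna <- NULL
  if (!is.null(rna)) {
    if (length(rna_kept) < 4)
      stop("de: fewer than 4 RNA cells pass QC; check rna thresholds vs the ",
           "simulated gene universe")
    norm_rna <- normalize_rpm_log(rna[rna_kept, , drop = FALSE])
    rna_labels <- labels_all[rownames(norm_rna)]
    degs <- wilcoxon_de_all(norm_rna, rna_labels, min_pct = config$de_min_pct,
                            min_logfc = config$de_min_logfc,
                            alpha = config$de_alpha)
    hvg <- select_hvg(norm_rna, config$n_hvg)
    write_de_table(degs, file.path(out, "degs.tsv"))
    keep_file(file.path(out, "degs.tsv"))
    say("de: ", sum(degs$significant), " significant gene/type pairs")
  }
  stages$de <- list(n_significant = sum(degs$significant %||% 0))

  ## -- dap ------------------------------------------------------------------
  dap <- call_cell_type_specific_peaks(peak_m, labels_all[rownames(peak_m)],
                                       alpha = config$dap_alpha,
                                       peaks = if (!is.null(peaks$name)) peaks)
  write_dap_table(dap, file.path(out, "daps.tsv"))
  keep_file(file.path(out, "daps.tsv"))
  say("dap: ", nrow(dap$calls), " cell-type-specific peaks")
  stages$dap <- list(n_specific = nrow(dap$calls))

  ## -- stratify -------------------------------------------------------------
  cls <- classify_peak_elements(peaks, genes,
                                config$promoter_upstream_annotation)
  strat <- data.frame(peaks, element = as.character(cls))
  data.table::fwrite(strat, file.path(out, "peak_elements.tsv"), sep = "\t",
                     quote = FALSE, scipen = 50)
  keep_file(file.path(out, "peak_elements.tsv"))
  stages$stratify <- as.list(table(cls))

  ## -- link -----------------------------------------------------------------
  links <- NULL
  if (!is.null(degs)) {
    links <- link_daps_to_degs(dap, degs, genes, window = config$cre_window)
    write_cre_table(links, file.path(out, "cre_links.tsv"))
    keep_file(file.path(out, "cre_links.tsv"))
    say("link: ", nrow(links), " CRE links")
  }
  stages$link <- list(n_links = nrow(links %||% data.frame()))

  ## -- concordance ----------------------------------------------------------
  if (!is.null(norm_rna)) {
    shared <- intersect(rownames(norm_rna), rownames(act_m))
    norm_act <- normalize_rpm_log(act_m[shared, , drop = FALSE] + 0)
    rna_prof <- cluster_mean_zscores(norm_rna, labels_all[rownames(norm_rna)])
    atac_prof <- cluster_mean_zscores(norm_act, labels_all[shared])
    conc <- concordance_matrix(rna_prof, atac_prof, hvg)
    write_concordance_table(conc, file.path(out, "concordance.tsv"))
    keep_file(file.path(out, "concordance.tsv"))
    stages$concordance <- list(
      n_genes = attr(conc, "n_genes"),
      argmax_match = sum(colnames(conc)[apply(conc, 1, which.max)] ==
                           rownames(conc)))
  }

  ## -- stages ---------------------------------------------------------------
  if (!is.null(traj)) {
    stage_m <- simulate_stage_peak_matrix(sim, truth, traj)
    assign <- bin_cells_into_stages(
      stats::setNames(traj$cells$pseudotime, traj$cells$barcode),
      stats::setNames(traj$cells$lineage, traj$cells$barcode),
      sim$stage_graph, sim$lineage_paths)
    trans <- stage_transition_daps(stage_m, assign, sim$stage_graph,
                                   alpha = config$dap_alpha)
    data.table::fwrite(assign, file.path(out, "stage_assignment.tsv"),
                       sep = "\t", quote = FALSE, scipen = 50)
    write_transition_table(trans, file.path(out, "stage_transitions.tsv"))
    keep_file(file.path(out, c("stage_assignment.tsv",
                               "stage_transitions.tsv")))
    say("stages: ", nrow(trans), " transition DAP calls over ",
        nrow(sim$stage_graph$edges), " edges")
    stages$stages <- list(n_transition_calls = nrow(trans))
  }

  ## -- gwas -----------------------------------------------------------------
  if (!is.null(snps)) {
    ov <- overlap_snps_with_peaks(snps$snps, peaks, dap, genes)
    write_snp_overlap_table(ov, file.path(out, "snp_overlap.tsv"))
    keep_file(file.path(out, "snp_overlap.tsv"))
    say("gwas: ", sum(ov$in_peak), "/", nrow(ov), " SNPs in peaks")
    stages$gwas <- list(n_snps = nrow(ov), n_in_peak = sum(ov$in_peak))
  }

  ## -- manifest -------------------------------------------------------------
  files <- unique(files[file.exists(files)])
  digests <- tools::md5sum(files)
  names(digests) <- sub(paste0("^", out, "/?"), "", names(digests))
  manifest <- list(
    package_version = as.character(utils::packageVersion("atacdap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = sim$seed,
    parameters = list(
      bin_size_atac = config$bin_size_atac,
      bin_size_pseudobulk = config$bin_size_pseudobulk,
      top_bin_fraction = config$top_bin_fraction,
      promoter_upstream_qc = config$promoter_upstream_qc,
      promoter_upstream_annotation = config$promoter_upstream_annotation,
      dap_alpha = config$dap_alpha, de_min_pct = config$de_min_pct,
      de_min_logfc = config$de_min_logfc, de_alpha = config$de_alpha,
      n_hvg = config$n_hvg, cre_window = config$cre_window,
      activity_mode = config$activity_mode,
      activity_upstream = config$activity_upstream),
    stages = stages,
    outputs = as.list(digests))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
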