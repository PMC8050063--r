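## Pseudotime stage binning and stage-transition chromatin dynamics.
## Pseudotime and lineage labels are inputs (from an external trajectory tool
## or the synthetic generator); this module bins cells into developmental
## stages along a rooted stage graph, then calls differentially accessible
## peaks between each stage and its ancestral stage (and between sibling
## branches) with the same one-sided Fisher + BH machinery as the cell-type
## caller. Descendant-enriched peaks are "opened", ancestor-enriched peaks
## "closed".

#' Construct a rooted stage graph
#'
#' @param from,to Character vectors of directed edges (ancestor -> descendant)
#'   forming a rooted tree: exactly one root, no cycles, one ancestor per
#'   non-root stage.
#' @return An object of class `stage_graph` with elements `stages`, `root`,
#'   `edges` and `parent` (named vector).
#' @export
stage_graph <- function(from, to) {
  edges <- data.frame(from = as.character(from), to = as.character(to),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(edges$to))
    stop("stage graph: a stage has more than one ancestor")
  stages <- union(edges$from, edges$to)
  roots <- setdiff(edges$from, edges$to)
  if (length(roots) != 1)
    stop("stage graph must have exactly one root (found ",
         length(roots), ")")
  parent <- stats::setNames(edges$from, edges$to)
  ## cycle check: walk up from every stage, must reach the root
  for (s in stages) {
    seen <- character(); cur <- s
    while (cur %in% names(parent)) {
      if (cur %in% seen) stop("stage graph contains a cycle at ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
    if (cur != roots) stop("stage ", s, " is not connected to the root")
  }
  structure(list(stages = stages, root = roots, edges = edges,
                 parent = parent), class = "stage_graph")
}

#' @method print stage_graph
#' @export
print.stage_graph <- function(x, ...) {
  cat("<stage_graph> ", length(x$stages), " stages, root=", x$root, "\n",
      sep = "")
  invisible(x)
}

#' Stages in the subtree rooted at a stage (inclusive)
#'
#' @param graph A [stage_graph()].
#' @param stage Stage label.
#' @return Character vector of descendant stages, including `stage`.
#' @export
stage_descendants <- function(graph, stage) {
  stopifnot(inherits(graph, "stage_graph"), stage %in% graph$stages)
  out <- stage
  repeat {
    more <- graph$edges$to[graph$edges$from %in% out & !
                             graph$edges$to %in% out]
    if (!length(more)) break
    out <- c(out, more)
  }
  out
}

#' The default 15-stage kidney differentiation graph
#'
#' Nephron progenitors (NP0-NP3) branch into the podocyte lineage
#' (Podo1-Podo3) and, via intermediate cells (IM1-IM2), into proximal tubule
#' (PT1-PT3), loop of Henle (LOH1-LOH2) and distal convoluted tubule (DCT).
#'
#' @return A [stage_graph()] over 15 stages.
#' @export
kidney_stage_graph <- function() {
  stage_graph(
    from = c("NP0", "NP1", "NP2", "NP3", "Podo1", "Podo2", "NP3", "IM1",
             "IM2", "PT1", "PT2", "IM2", "LOH1", "IM2"),
    to = c("NP1", "NP2", "NP3", "Podo1", "Podo2", "Podo3", "IM1", "IM2",
           "PT1", "PT2", "PT3", "LOH1", "LOH2", "DCT"))
}

#' Root-to-leaf lineage paths of the kidney stage graph
#'
#' @return Named list of ordered stage vectors (podo, pt, loh, dct).
#' @export
kidney_lineage_paths <- function() {
  trunk <- c("NP0", "NP1", "NP2", "NP3")
  list(podo = c(trunk, "Podo1", "Podo2", "Podo3"),
       pt = c(trunk, "IM1", "IM2", "PT1", "PT2", "PT3"),
       loh = c(trunk, "IM1", "IM2", "LOH1", "LOH2"),
       dct = c(trunk, "IM1", "IM2", "DCT"))
}

#' Bin cells into developmental stages by pseudotime quantiles
#'
#' Within each lineage, cells are split into as many equal-count bins as the
#' lineage's stage path has stages (bin sizes differ by at most one cell),
#' in pseudotime order; the i-th bin receives the i-th stage label of the
#' path. Stage boundaries are reported as an attribute.
#'
#' @param pseudotime Named numeric vector in `[0, 1]`, barcode -> pseudotime.
#' @param lineage Named character vector, barcode -> lineage label.
#' @param graph A [stage_graph()]; every path stage must be a graph stage,
#'   and the union of path stages must cover the graph.
#' @param stages_per_lineage Named list, lineage label -> ordered stage path.
#' @return data.frame: `barcode`, `lineage`, `pseudotime`, `stage`; attribute
#'   `boundaries` holds per-lineage stage pseudotime ranges.
#' @export
bin_cells_into_stages <- function(pseudotime, lineage, graph,
                                  stages_per_lineage) {
  stopifnot(inherits(graph, "stage_graph"))
  if (is.null(names(pseudotime)) || is.null(names(lineage)))
    stop("pseudotime and lineage must be named by barcode")
  barcodes <- names(pseudotime)
  lineage <- lineage[barcodes]
  if (anyNA(lineage)) stop("every barcode needs a lineage label")
  bad <- setdiff(unlist(stages_per_lineage), graph$stages)
  if (length(bad)) stop("unknown stages in paths: ", paste(bad, collapse = ", "))
  if (!setequal(unlist(stages_per_lineage), graph$stages))
    stop("lineage paths must cover every stage of the graph")
  out <- list(); bounds <- list()
  for (l in names(stages_per_lineage)) {
    path <- stages_per_lineage[[l]]
    L <- length(path)
    bc <- barcodes[lineage == l]
    if (length(bc) == 0) next
    if (length(bc) < L)
      stop("lineage ", l, " has fewer cells (", length(bc),
           ") than stages (", L, ")")
    pt <- pseudotime[bc]
    o <- order(pt, bc)                   # barcode tie-break: deterministic
    bin <- ceiling(seq_along(o) * L / length(o))
    stage <- character(length(o)); stage[o] <- path[bin]
    out[[l]] <- data.frame(barcode = bc, lineage = l, pseudotime = unname(pt),
                           stage = stage, stringsAsFactors = FALSE)
    bounds[[l]] <- do.call(rbind, lapply(seq_len(L), function(i) {
      p <- pt[o][bin == i]
      data.frame(lineage = l, stage = path[i], min_pseudotime = min(p),
                 max_pseudotime = max(p), n_cells = length(p))
    }))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "boundaries") <- do.call(rbind, bounds)
  res
}

## One bidirectional (opened/closed) stage comparison over all peaks.
stage_pair_daps <- function(m, cells_anc, cells_desc, alpha) {
  acc_a <- Matrix::colSums(m[cells_anc, , drop = FALSE] != 0)
  acc_d <- Matrix::colSums(m[cells_desc, , drop = FALSE] != 0)
  na <- length(cells_anc); nd <- length(cells_desc)
  p_open <- bh_adjust(fisher_exact_greater(acc_d, nd - acc_d, acc_a, na - acc_a))
  p_close <- bh_adjust(fisher_exact_greater(acc_a, na - acc_a, acc_d, nd - acc_d))
  list(opened = which(p_open < alpha), closed = which(p_close < alpha),
       p_open = p_open, p_close = p_close,
       frac_anc = acc_a / na, frac_desc = acc_d / nd)
}

#' Stage-to-stage differentially accessible peaks
#'
#' For each edge of the stage graph, tests every peak in both directions
#' between the ancestor and descendant stage cells with one-sided Fisher
#' tests, BH-adjusted per direction across peaks. Peaks significantly more
#' accessible in the descendant are "opened", in the ancestor "closed". The
#' root stage yields no record of its own.
#'
#' @param m Binary cell-by-peak matrix covering the assigned cells.
#' @param assignment data.frame from [bin_cells_into_stages()] (or any frame
#'   with `barcode` and `stage`).
#' @param graph A [stage_graph()].
#' @param alpha Significance level on adjusted p (default 0.05).
#' @return data.frame of transition DAPs: `from`, `to`, `peak`, `direction`
#'   (opened/closed), `p_adj`, `fraction_ancestor`, `fraction_descendant`.
#' @export
stage_transition_daps <- function(m, assignment, graph, alpha = 0.05) {
  stopifnot(inherits(graph, "stage_graph"))
  stage_of <- stats::setNames(assignment$stage, assignment$barcode)
  out <- list()
  for (i in seq_len(nrow(graph$edges))) {
    anc <- graph$edges$from[i]; desc <- graph$edges$to[i]
    ca <- names(stage_of)[stage_of == anc]
    cd <- names(stage_of)[stage_of == desc]
    if (length(ca) == 0 || length(cd) == 0)
      stop("empty stage on edge ", anc, " -> ", desc)
    r <- stage_pair_daps(m, ca, cd, alpha)
    mk <- function(idx, dir, padj)
      if (length(idx)) data.frame(
        from = anc, to = desc, peak = colnames(m)[idx], direction = dir,
        p_adj = padj[idx], fraction_ancestor = r$frac_anc[idx],
        fraction_descendant = r$frac_desc[idx], stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- mk(r$opened, "opened", r$p_open)
    out[[length(out) + 1]] <- mk(r$closed, "closed", r$p_close)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(from = character(), to = character(), peak = character(),
                      direction = character(), p_adj = numeric(),
                      fraction_ancestor = numeric(),
                      fraction_descendant = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Branch-vs-branch differentially accessible peaks
#'
#' Pools the cells of two disjoint stage sets (e.g. two descendant lineages
#' after a bifurcation) and tests every peak in both directions.
#'
#' @param m Binary cell-by-peak matrix.
#' @param assignment data.frame with `barcode` and `stage`.
#' @param branch_a,branch_b Disjoint, non-empty stage sets.
#' @param alpha Significance level (default 0.05).
#' @return List with `enriched_a` and `enriched_b`: data.frames of peaks
#'   (`peak`, `p_adj`, `fraction_a`, `fraction_b`).
#' @export
branch_divergence_daps <- function(m, assignment, branch_a, branch_b,
                                   alpha = 0.05) {
  if (length(intersect(branch_a, branch_b)))
    stop("branches must be disjoint stage sets")
  stage_of <- stats::setNames(assignment$stage, assignment$barcode)
  ca <- names(stage_of)[stage_of %in% branch_a]
  cb <- names(stage_of)[stage_of %in% branch_b]
  if (length(ca) == 0 || length(cb) == 0) stop("both branches need cells")
  r <- stage_pair_daps(m, cells_anc = cb, cells_desc = ca, alpha)
  ## "descendant" slot = branch a, so opened = enriched in a
  mk <- function(idx, padj) data.frame(
    peak = colnames(m)[idx], p_adj = padj[idx],
    fraction_a = r$frac_desc[idx], fraction_b = r$frac_anc[idx],
    stringsAsFactors = FALSE, row.names = NULL)
  list(enriched_a = mk(r$opened, r$p_open), enriched_b = mk(r$closed, r$p_close))
}

#' Write a stage-transition DAP table
#'
#' @param x Output of [stage_transition_daps()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_transition_table <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, scipen = 50)
  invisible(path)
}
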