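---
title: "Cell-type-specific chromatin accessibility: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-specific chromatin accessibility: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdap)
```

# The problem and the model

Single-nucleus ATAC-seq produces, per cell, a few thousand sequenced
fragments marking transposase-accessible chromatin. At that depth a
regulatory element in one cell is effectively a Bernoulli observation: open
and detected (one or more overlapping fragments) or not. `atacdap` therefore
works throughout on **binarized** cell-by-feature matrices and treats
differential accessibility as a contingency problem.

The core procedure calls a peak *specific* to a cell type when it is
significantly enriched against **every** other cell type: for each
(peak, focal type, other type) triple we form the 2×2 table of
accessible/inaccessible cell counts, compute the one-sided Fisher exact
p-value (upper hypergeometric tail, focal enrichment), BH-adjust within each
(focal, other) family across all peaks, and require all adjusted p-values
below α = 0.05. The modelling assumptions are: cells are exchangeable within
a type, binarization discards no relevant signal at single-cell depth, and
the peak universe is fixed and disjoint (overlapping peaks must be merged
first, book-ended intervals merging together).

Two properties of the rule matter in practice. One-sidedness makes type
assignment unique — a peak enriched "in both A and B" fails A-vs-B or
B-vs-A, so it is specific to neither, which is the intended reading of
"stringently open in one type". And because the binding constraint is the
*maximum* adjusted p-value over comparisons, power is set by the focal type's
hardest competitor, not by the average.

## Sidedness and the BH family

The test's sidedness and the family over which BH is applied are genuine
design choices:

* **Sidedness.** We default to one-sided enrichment because the target
  concept — a peak open in exactly one type — is directional, and because it
  buys the uniqueness guarantee above. A two-sided variant (doubled smaller
  tail, capped at 1) is available behind `alternative = "two.sided"`.
* **BH family.** Adjustment is per (focal, other) comparison across peaks:
  each pairwise comparison is one peak-level multiple-testing problem, the
  convention of peak-level FDR control within a comparison. Pooling all
  comparisons into one family (`bh_family = "global"`) is available; it is
  slightly more conservative when type counts differ.

## Other statistical components

* **Wilcoxon differential expression.** RPM-log normalization
  (`log(1 + 10^6 x / total)`, natural log; the 10^4-scale variant via
  `scale=`), detection and fold-change prefilters *before* testing
  (`max(pct_in, pct_out) >= 0.25`, `|logFC| >= 0.25` with logFC =
  `log(mean(expm1(norm)) + 1)` difference), two-sided rank-sum tests on the
  survivors, BH across tested genes. P-values are exact (enumeration
  distribution) when the smaller group has ≤ 10 tie-free observations,
  otherwise the normal approximation with continuity and tie correction;
  the suite checks the exact path against full enumeration to 1e-12 and the
  approximate path against the exact distribution at m = n = 20.
  Note the prefilter deliberately shrinks the BH family, so the planted-truth
  FDR of the full procedure runs slightly above the nominal 0.05 — an honest
  property of the published recipe, visible in the acceptance numbers.
* **Element stratification.** Overlap classes are resolved by the fixed
  priority exon > 5′UTR > 3′UTR > intron > promoter > distal. Promoters are
  strand-aware upstream-only windows (5 kb default; the 2 kb variant can only
  promote peaks, never demote them to distal, and the suite asserts that
  monotonicity). Intron is transcript span minus the exon union, per gene;
  single-exon genes contribute none. UTR and exon tracks are taken as given;
  where a UTR lies inside an exon the priority rule resolves it.
* **CRE linking.** A link requires same-type specificity of peak and gene,
  the *nearer peak edge* within ±100 kb of the TSS (any part of the peak in
  the window qualifies; edge-vs-midpoint is not pinned down by the source
  convention, and the nearer edge is the inclusive reading), and no overlap
  of the single TSS base with the half-open peak. Distances are signed
  negative upstream in the gene's orientation.
* **Nearest gene.** Anchored at the TSS (gene-body distance is the obvious
  alternative; TSS anchoring is deterministic and matches the linking
  convention), ties broken by smaller TSS coordinate then gene id.

# Coordinate conventions

All internal coordinates are 0-based half-open (BED). Overlap is
`a.start < b.end && b.start < a.end` on a shared chromosome; a fragment
ending exactly at a peak's start does not overlap it; a SNP at a peak's `end`
coordinate is outside. GTF input (1-based inclusive) is converted at the
reader boundary. Interval plumbing (merge, tiling, nearest, overlap counting)
is delegated to GenomicRanges/IRanges with the ±1 shift confined to two
converter functions; peak merging uses `reduce`, which also merges
book-ended intervals — the same semantics used to build the merged peak
universe in this analysis tradition.

One deliberate asymmetry: the binarized cell-by-bin and cell-by-peak matrices
assign a fragment to *every* feature it overlaps (a fragment spanning a 5 kb
boundary marks both bins), while the pseudobulk profile counts each fragment
once, in the 10 kb bin containing its start, so that per-bin counts sum
exactly to the retained fragment count. Sex chromosomes and the
mitochondrial chromosome are excluded from pseudobulk profiles; mitochondrial
fragments are dropped from the cell-by-bin matrix but counted in the QC
denominator.

# Quality control

Per-cell ATAC covariates are computed on deduplicated fragments (unique
(chrom, start, end, barcode)): fragment count, mitochondrial fragment ratio,
and promoter ratio with *all* unique fragments in the denominator (the
alternative — passing fragments only — is not what "fraction of fragments in
promoters" says). Filters follow the quoted wording literally: counts kept
inclusively in [1000, 40000] ("ranging from 1000 to 40,000"), mito ratio
strictly below 0.10 ("less than 10%" — a cell at exactly 10 % is dropped;
the boundary is unstated and this is the stricter documented choice),
promoter ratio at least 0.20 (the complement of "< 20 % … filtered out").
RNA cells keep 200–3000 detected genes and mito ≤ 50 % — the exclusions
"< 200", "> 3000", "> 50" are strict, so the boundary values survive. The
QC promoter set is TSS ± 2 kb per gene: the upstream toolchain's definition
is unstated, so this common convention is the default and it is
configurable; element stratification uses its own, explicitly stated, 5 kb
upstream promoters.

# The synthetic study and what it does (not) show

`sim_config()` defines a fully self-contained study whose defaults are the
reference conditions used by the test-suite and the acceptance script:

* **ATAC**: 5 cell types × 200 cells, 1,000 disjoint 400 bp peaks on five
  10 Mb autosomes, 50 planted type-specific peaks per type; per-cell peak
  accessibility Bernoulli with baseline `p0 = 0.05` and planted elevation
  `p1 = 0.6`. Fragment realizations draw per-cell totals log-normally
  (median 1,500, clamped to [1,100, 30,000], inside the QC window), inject
  3 % mitochondrial and 35 % promoter-window fragments to give the QC
  covariates realistic values, and place the remainder uniformly outside
  peaks. 4 % extra cells are planted QC violators, one rule each.
* **RNA**: 500 genes, negative-binomial counts (mean 2, size 2) with
  20 planted markers per type elevated 2^2 = 4-fold and coupled to same-type
  planted peaks within ±100 kb of the TSS — so DE, linking and concordance
  all have recoverable truth. The gene universe and marker share are sized
  so that clean cells clear the 200-detected-genes RNA filter (~75 %
  detection × 500 genes) and the 100 coupled markers carry the
  cross-modality profile correlations; promoter-fragment placement favours
  each type's markers, giving fragment-derived gene-activity scores genuine
  cell-type signal.
* **Trajectory**: the 15-stage kidney graph (NP0→NP1→NP2→NP3 branching to
  Podo1–3 and, via IM1–IM2, to PT1–3, LOH1–2 and DCT). Each root-to-leaf
  lineage receives 150 cells per stage along its path with uniform
  pseudotime, so trunk stages pool cells from every lineage passing through
  them; 10 null peaks per edge are planted as transition events (half
  opening p0→p1 in the descendant subtree, half closing).
* **GWAS**: 200 SNPs, 30 % placed uniformly inside planted specific peaks,
  the rest uniformly outside all peaks.

Everything is deterministic under the config seed; sub-generators use fixed
offsets so each piece reproduces in isolation.

The generator emulates the *statistical* structure the methods assume —
Bernoulli accessibility, NB expression, planted couples, stage flips. It
does **not** emulate read-level sequence, doublets, ambient RNA, batch
effects, LD between SNPs, co-accessibility structure, or realistic genome
annotation density. Passing tests therefore demonstrate that the procedures
recover the structure they model, at these effect sizes and sample sizes —
not that the thresholds are optimal for any real tissue.

# Numerical and procedural choices

* Fisher p-values come from the hypergeometric tail (`phyper`), validated
  against brute-force `choose()` summation for every table with N ≤ 30 to
  1e-12. The all-zero table returns 1 (`P(X ≥ 0)`).
* BH is the standard step-up (via `p.adjust`), validated against the literal
  definition on 1,000 random vectors.
* Top-5 % bin removal drops exactly `floor(0.05 · n_bins)` columns ranked by
  column sum, ties at the cutoff resolved by genomic order — deterministic
  where the source convention is silent.
* Stage binning uses equal-count pseudotime quantiles within lineage (bin
  sizes differ by ≤ 1 cell), with per-stage boundaries reported so an
  alternative rule can be compared; the original binning rule is not
  published. Quantile binning misassigns a few cells near stage boundaries,
  which leaks a small amount of signal to edges adjacent to a planted flip —
  the stage-transition FDR in the acceptance output (~0.05–0.08 pooled over
  seeds) includes that effect.
* Opened/closed classification uses two one-sided tests with BH per
  direction rather than one two-sided test with a sign, keeping directional
  FDR explicit and matching the specificity caller; both directions cannot
  be significant for one peak since the two tail probabilities overlap at
  the observed table.
* Cluster z-scores divide by the sample SD (n−1, as `scale()` does;
  two clusters with means 2 and 4 give ∓0.707), with the population
  convention behind a flag. Means are taken first, z-scores second, and any
  gene subsetting (HVGs) happens after z-scoring. The HVG set for
  concordance comes from the RNA modality, intersected with the activity
  matrix's genes.
* Problem sizes throughout the suite and acceptance script (10 seeds for
  DAP recovery, 5 for the null, 3 for DE and stage transitions, the 5-type ×
  200-cell reference study) are the package's chosen reference conditions:
  large enough that the binomial recovery bounds are stable, small enough
  to iterate on quickly.

# Limitations

* Clustering, embedding, batch correction, trajectory inference, motif
  enrichment, co-accessibility and regulon analysis are out of scope; cluster
  labels, pseudotime and lineage assignments are consumed as inputs.
* The DE prefilter-then-BH recipe does not strictly control FDR at 0.05
  against planted truth (see above); users wanting strict control should
  test all genes and adjust globally.
* `nearest_gene` and the CRE linker assume one transcript model per gene;
  multi-isoform annotations must be reduced to canonical models first.
* The two-sided Fisher option uses the doubled-tail convention, which is
  conservative relative to the minimum-likelihood method for asymmetric
  margins.
* Liftover is not performed; SNP inputs must already be in the target
  genome's coordinates.
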