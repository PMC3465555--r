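---
title: "Methods: screening for direct transcription-factor targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening for direct transcription-factor targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscreen)
```

## The problem

A transcriptional repressor such as Tcf3 in mouse embryonic stem cells
binds thousands of genomic sites, but only a subset of the genes near
those sites actually respond when the repressor is removed. The screen
implemented here identifies *candidate direct targets* by requiring two
independent lines of evidence per gene: the factor binds near the gene
(ChIP-seq), and the gene is derepressed — upregulated — when the factor
is inactivated (differential expression in two independent perturbation
studies). The package also characterises how several pluripotency
factors share genomic territory, through binary occupancy matrices,
correlation-based clustering, and region/target-level intersections.

## Coordinates and interval algebra

All coordinates are 0-based, half-open (the BED convention), including
the `tss` column of the annotation TSV. Two intervals overlap iff they
share at least one base; abutting half-open intervals (`[0,10)` and
`[10,20)`) do not overlap but are merged by `merge_intervals()`, which
returns the minimal disjoint covering of the base-level union.
Chromosome names are matched as exact strings — no silent "chr" prefix
normalization (an explicit `normalize_chrom` flag exists on
`read_bed()`), because silent renaming corrupts intersections.
Internally the interval operations are delegated to
GenomicRanges/IRanges; the package's tests verify them against
independent per-base brute-force oracles.

## Peak-to-gene assignment

The mapping rule is deliberately uniform across all factors:

* if a peak lies within `tss_window` (default 100 bp) of a TSS, it is
  associated with that gene **alone** (`tss_proximal` link);
* otherwise the nearest TSS within `flank` (default 50 kb) on each side
  of the peak midpoint contributes one `flanking` link, so a peak links
  at most `max_genes_per_peak` (default 2) genes;
* peaks with no qualifying TSS contribute nothing.

Distance is measured from the peak *interval*: a TSS inside the peak has
distance 0, and a TSS one base past the exclusive end has distance 1.
This is the most permissive reading and degrades gracefully for wide
peaks; a summit-anchored distance is available via
`assignment_rule(anchor = "summit")` for peak sets that carry summit
annotation. The window boundary is inclusive ("within 100 bp" includes
a TSS at exactly 100 bp). Equidistant ties are broken deterministically
by (chromosome order, tss, gene_id). Genes carry a single TSS each;
annotations with alternative TSSs should be expanded to one record per
TSS upstream, with `target_genes()` deduplicating at reporting time.

Because ChIP efficiency differs between antibodies and experiments, raw
peak counts are not comparable across factors. `top_n_peaks()` keeps
each factor's N highest-scoring peaks (default 5,000 in
`pipeline_config()`) before co-binding comparisons. The ranking
statistic is the BED score column; ties are broken by genomic position
so the selection is deterministic.

## Co-binding structures

`binary_peak_matrix()` builds the region × factor occupancy matrix over
the merged union of all factors' peaks, so every row has at least one 1.
`cluster_factors()` computes pairwise distances 1 − Pearson *r* between
the binary columns and clusters them agglomeratively (average linkage by
default; complete and single are available — the choice is a convention,
and average linkage is the common default for correlation-based TF
clustering). Zero-variance columns make the correlation undefined and
are a named error rather than being silently dropped. Columns are
ordered by factor name before clustering so ties resolve
deterministically.

`region_venn()` counts merged universe regions by the subset of inputs
overlapping each region. Counting merged regions (rather than each
factor's original peaks) is the only choice whose cells sum to a
well-defined total — the universe size; a secondary `count = "peaks"`
mode is provided for comparisons against per-peak counting, whose cells
instead sum to the total peak number. A "bound by at least one of"
composite (e.g. O/S/T = Oct4/Sox2/Tcf3) is formed by top-N-restricting
each member individually and then merging. Replicate peak files for one
factor are concatenated and merged by default (`replicate_mode =
"union"`, scores propagated as the maximum over contributing peaks);
an `"intersect"` mode keeps only bases covered by every replicate.

## The enrichment test

With a universe of N testable genes, K bound genes, n responders and an
overlap of k, `hypergeometric_enrichment()` reports the upper tail
P(X ≥ k) of the hypergeometric distribution — the chance of an overlap
at least as large under sampling without replacement. The test is
one-sided and uncorrected because the screen tests a single hypothesis.
The universe defaults to the genes assayed in **both** expression
studies: a gene must be assayable to be a responder, and this is the
least-biased reproducible default (it is overridable). The fold-change
filter is strict (`> 1.4` excludes exactly 1.4), and the mirrored
control screen on downregulated genes uses `fold change < 1/1.4` via
`direction = "down"`. Cross-study gene matching is case-folded symbol
matching by default. When the responder set is empty the p-value is
reported as 1 with a warning flag rather than failing.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure of the study's
inputs so the whole pipeline can be validated without downloads:

* **Annotation** — TSSs uniform without replacement per chromosome,
  strands Bernoulli(0.5).
* **Peaks** — shared "master" regions are drawn first; factor f occupies
  each with probability a_f, where the a_f reproduce the requested
  pairwise co-binding probabilities through the rank-1 relation
  ρ_fg = a_f·a_g (exact for three factors, log-least-squares otherwise;
  infeasible matrices are config errors). Master intervals are drawn
  once, so fully co-bound factors occupy identical coordinates. A
  `tss_targeting_fraction` of each factor's peaks is centered on gene
  TSSs; these genes form the factor's known true target set, and every
  planted candidate gene receives a TSS peak from every factor.
  TSS-targeted genes are preferentially chosen among genes with
  *isolated* promoters (no neighbouring TSS within 2.5 kb), so the
  assignment rule provably links the planted peak to the intended gene
  and ground truth is well defined. Peak widths are truncated normal
  (minimum 50 bp); scores are exponential so top-N selection is
  non-degenerate.
* **Expression** — planted candidates draw fold changes from `fc_up`
  independently in each study; all other genes draw from `fc_null`
  (median 1). RPKM is lognormal.

Each stage draws from its own named RNG stream derived from the single
config seed, so adding a stage never perturbs earlier stages' draws and
every output is a pure function of (config, seed).

Default conditions were fixed once as a realistic desk-scale study:
1,000 genes on 2 chromosomes of 5 Mb (one gene per ~10 kb, roughly
mammalian gene density), 3 factors × 500 peaks of mean width 300 bp,
pairwise co-binding 0.5, TSS-targeting fraction 0.3, 20 planted
candidates, `fc_up` lognormal(log 2, 0.05) — a strong, tight planted
effect centered on 2-fold — and `fc_null` lognormal(0, 0.12), a light
tail under which a double >1.4-fold false call has probability ≈ 7×10⁻⁶
per gene. What the generator does *not* emulate: probe-level microarray
noise, correlated fold-change errors between studies, mappability and
peak-calling artefacts, multi-TSS genes, and non-uniform gene spacing.
Passing tests therefore demonstrate the pipeline's correctness and
calibration under the stated model, not performance on any particular
real data set.

## Validation strategy and problem sizes

The test suite checks every operation against an independent
brute-force oracle: per-base coverage and labeling for merge/overlap and
region Venns (toy chromosomes, ≤ 100 kb), literal rule enumeration for
peak-to-gene assignment (200 random instances, ≤ 50 genes × ≤ 100
peaks), exhaustive subset enumeration for the hypergeometric tail
(every margin with N ≤ 12), and a naive O(k³) agglomeration for
clustering. End-to-end, the screen recovers exactly the planted
candidate set in ≥ 95% of 20 seeds under the default conditions, and
with no planted signal the enrichment test rejects at 0.05 in no more
than a chance fraction of 200 small-scale simulations — the
hypergeometric null is exactly valid there because binding and
expression are generated independently, so the p-value is
super-uniform. These problem sizes keep the whole suite within a few
minutes on one CPU while leaving each property statistically
informative.

## Known limitations

* The per-factor-peak Venn mode and the merged-region mode can give
  different cell totals by construction; published Venn counts rarely
  state which convention was used, so both are exposed.
* The rank-1 co-binding model cannot represent every pairwise
  probability matrix (e.g. two strongly co-bound factors each nearly
  independent of a third); such matrices are rejected explicitly.
* The enrichment universe choice materially affects p-values; the
  default (genes assayed in both studies) should be overridden when a
  better-defined universe exists.
* Run manifests embed a timestamp; determinism guarantees cover the
  analysis outputs (tables, JSON results), not the manifest bytes.
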