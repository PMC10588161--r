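---
title: "Methods: comparative analysis of hypomethylated region patterns"
author: "hmratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of hypomethylated region patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmratlas)
```

## The problem

Whole-genome bisulfite sequencing yields a methylation fraction for every
CpG, and segmentation of those fractions produces hypomethylated regions
(HMRs): contiguous stretches of CpGs with low methylation, called per cell
type. Outside promoters, HMRs mark putative enhancers, and how they are
shared across cell types and arranged along the genome carries information
about when and where a cell's regulatory program was established.
`hmratlas` implements the comparative layer of that analysis: it consumes
per-cell-type HMR calls (BED) and per-CpG methylation tracks (bedGraph)
and asks how HMRs distribute across cell types (methylation matrix and
unsupervised grouping), across the genome (spacing against a shuffle null,
cluster linking), across developmental time (establishment and retention
along a lineage), and against genes and external annotations
(TAD-constrained nearest-expressed-gene assignment, overlap tables).

All coordinates are 0-based half-open (BED convention). Overlap between
two regions always means at least one shared base pair. The gap between
two intervals is the distance between their facing edges, zero for
overlapping or bookended intervals; `bedtools closest` reports 1 for
bookended features, a documented divergence that is immaterial at the
kilobase-scale thresholds used here (6,000 and 500,000 bp).

## Non-coding filtering

Promoter HMRs are nearly invariant across cell types, so the analysis
removes them first. The exclusion list is built from a gene table: a
promoter window around each TSS — 2,000 bp upstream and 1,000 bp
downstream, mirrored by strand and clipped at zero — plus every exon,
merged. The asymmetric window is what makes strand-awareness necessary;
the TSS itself is elected from the gene's start (`+`) or end (`-`)
coordinate. An HMR is removed if it touches the exclusion list by one
base pair or is shorter than 50 bp. Blacklist overlap is checked before
length so the filter report's categories are disjoint and sum to the
input count; the filter is idempotent.

## Methylation matrix and unsupervised grouping

Consensus regions are the merged union of all cell types' filtered HMRs;
each consensus region records its contributing cell types. The matrix
holds the mean methylation of each consensus region in each cell type.
The mean is the unweighted average of per-CpG fractions within the region
(no coverage weighting, since the input bedGraph scores are plain
fractions); a coverage-weighted option exists but is off by default.
Regions without CpGs in a track yield missing cells, and rows with any
missing cell are dropped from clustering with a message — the simplest
defensible treatment, since imputation would manufacture methylation
values.

HMR groups come from k-means (k = 10 by default, chosen by the elbow
method over k = 1..12 in the original analysis). Initialization is
k-means++ followed by Lloyd iterations, with ten restarts keeping the
lowest within-group sum of squares. The seed fixes the stream, and rows
are put in a canonical sort order before seeding so the result does not
depend on how the caller ordered the matrix; determinism is guaranteed
per seed within this package, not bit-identically to any external
implementation. When the matrix has no more distinct rows than groups,
each distinct row becomes its own group with zero within-group sum of
squares rather than failing. A group is labeled by the cell types whose
group-center methylation is at or below 50% (inclusive). Cell-type
relationships are summarized by Ward (D2) hierarchical clustering of the
columns under Euclidean distance.

## Inter-HMR spacing and the shuffle null

For each HMR the observed statistic is the gap to its nearest neighbor on
the same chromosome; HMRs alone on a chromosome have no neighbor and are
omitted with a message. The null re-places every HMR uniformly at random
on its own chromosome among the start positions where it fits entirely
outside the exclusion list, preserving lengths and per-chromosome counts
(a chromosome-preserving null is the more conservative choice, retaining
per-chromosome density). Placement samples directly from the enumerated
legal starts, so no rejection loop is needed against the blacklist. By
default shuffled intervals may overlap one another, as `bedtools shuffle`
allows; a no-overlap mode places intervals sequentially and re-draws
conflicting ones, the same process the synthetic generator uses.
Each of the (by default 10,000) iterations is summarized by its mean
nearest-neighbor distance, and observed per-HMR distances are capped at
500 kb before testing.

Two comparison modes are provided. The `ranksum_means` mode applies the
Wilcoxon rank-sum test to the observed per-HMR distances against the
per-iteration null means. Its sample units are asymmetric — raw values
from a right-skewed distribution on one side, means on the other — and
because the mean of a skewed distribution exceeds its median, this
comparison rejects even under uniform placement. It is kept because it is
the form used in published work of this kind, and the report flags the
caveat. The `empirical` mode is the calibrated alternative: the observed
mean distance is ranked among the null means and the two-sided
permutation p-value is `(1 + tail count) / (n_iter + 1)`, doubled and
capped at one. Under the null the observed summary and the null summaries
are exchangeable, so this p-value is uniform up to discreteness;
calibration and power checks in the test suite use this mode.

## Cluster linking and spatial classification

Whitelist regions are the complement of the exclusion list. HMRs fully
contained in the same whitelist region are chained whenever consecutive
end-to-end gaps are at most 6 kb (inclusive, matching `bedtools merge -d`
semantics), so chains never cross a TSS or exon. Chains of three or more
are clusters; chains of exactly two are pairs; both thresholds are
configurable. Every non-coding HMR then receives exactly one class:

* `cluster_member` / `pair_member` — in a chain of the respective size;
* `unclustered` — no HMR of any kind (including promoter/exon-overlapping
  HMRs from the unfiltered call set) within 6 kb;
* `tss_exon_proximal` — only blacklist-overlapping HMRs within 6 kb;
* `residual` — a non-coding HMR within 6 kb but on the other side of a
  blacklist boundary.

The published category scheme is not exhaustive — the residual case falls
through it — so the explicit class is added rather than silently dropping
such HMRs or deducing their count by set subtraction; totals can
therefore differ slightly from subtraction-based counts when residuals
exist. The headline "clustered fraction" is clustered / (clustered +
unclustered), ignoring the intermediate classes so that cell types are
comparable.

## Lineage tracing

A lineage order arranges the cell types on a tree (default: embryonic
stem cell at the root, a multipotent progenitor, two differentiated
leaves). A stage's origin set holds its HMRs that overlap no ancestor
stage. Retention of an origin set in a descendant is reported in two
variants: direct (origin HMRs overlapping the descendant) and
path-conditioned (origin HMRs overlapping every stage down the path),
because multi-step comparisons in the source analysis condition on the
intermediate stage while single-step ones do not; both use the origin
count as denominator. Overlap is counted in units of the origin set — one
origin HMR overlapping several descendant HMRs counts once. Percentages
are rounded half-up to two decimals so printed reports are deterministic.

Derivation labels classify a target cell type's HMRs for annotation
export: `stem_derived` (overlaps stem and progenitor sets), then
`progenitor_derived` (progenitor but not stem), `cell_specific` (no
overlap with any panel set), and an explicit `other` for the remainder
(e.g. stem but not progenitor), which the three named groups alone do not
cover. The flow (Sankey) table assigns each target HMR one source
category by a fixed hierarchy — clustered progenitor HMR, unclustered
progenitor HMR, shared (any other progenitor overlap), cell-specific —
and cross-tabulates it against the target's own class. "Shared" is
interpreted as overlap with a progenitor HMR in the intermediate spatial
classes (pair/proximal/residual), which is what the hierarchy's ordering
implies.

## Gene assignment

Distance from a region to a gene is measured from the nearest region edge
to the TSS point, zero if the TSS lies inside the region. For each region
a candidate pool of the k = 100 nearest TSSs is drawn; pairs whose
spanning interval (region plus TSS) does not fit entirely inside a single
TAD are removed (containment in any one TAD suffices for nested or
overlapping TADs), as are genes with TPM of zero. The nearest survivor is
the assignment; for the expression contrast, the two nearest survivors
per region are kept (k = 2 mirrors the two-nearest variant of the source
method) and genes are deduplicated within each group before the rank-sum
comparison. Equidistant genes are ordered by (distance, gene id) — a
deterministic convention, since no tie rule is published. Cluster spans,
not member HMRs, are the regions for clustered groups. Distance-binned
comparisons use half-open bins [0, 10), [10, 50), [50, 100), [100, Inf)
kb, configurable since only the topmost bin's boundary is published;
bins with fewer than two genes in either group are flagged untested.

## Statistical kernels

The two tests used throughout are thin, validated surfaces over the
standard R implementations the analysis is defined in terms of:
`wilcox.test()` (exact for tie-free samples of at most 20 per side, else
normal approximation with tie and continuity correction; two-sided
p-values are the doubled tail capped at one) and `prop.test()`
(chi-square test of equal proportions, Yates continuity correction on by
default and removable by flag; the corrected p-value is never smaller
than the uncorrected one). Two degenerate cases are made explicit: fully
tied rank-sum data and pooled proportions of exactly zero or one both
return p = 1, since the group distributions are identical there and the
textbook statistics are undefined. The test suite checks both kernels
against independent oracles — full enumeration of labelings for the exact
rank-sum tail and a hand-written pooled-z chi-square — and verifies the
nominal 5% size by simulation.

## The synthetic lineage generator

Real HMR atlases cannot ship with a package, so every pipeline stage is
validated on simulated lineages with known ground truth. The generator
emulates the statistical structure the analysis assumes:

* a genome of 3 chromosomes x 10 Mb with 300 uniformly placed stranded
  genes (bodies 5-50 kb, four 150-bp exons) and 500-kb tiling TADs, from
  which the promoter/exon exclusion list is derived;
* a basal HMR set of 600 placed uniformly in the whitelist at the root;
* per transition, each parental HMR retained with probability 0.9
  (coordinates unchanged) plus 1,000 newly gained HMRs, each proximal
  with probability 0.35 — placed uniformly among legal starts within 6 kb
  of a randomly chosen existing HMR — and uniform otherwise; HMRs within
  a stage never overlap;
* log-normal HMR lengths with median 866 bp (sdlog 0.7, resampled below
  50 bp);
* per-CpG methylation at geometrically spaced positions (mean 100 bp),
  Beta(2, 18) inside HMRs and Beta(18, 2) outside (means 0.1 / 0.9);
* zero-inflated log-normal TPM, doubled for genes whose TAD contains an
  HMR cluster span.

The defaults echo the magnitudes reported for human data — roughly 60% of
differentiated-cell HMRs established early, about 35% of new HMRs arising
within 6 kb of an existing one, a median length near 866 bp — without
claiming to reproduce any dataset exactly. Every HMR carries its stage of
establishment and a proximal-placement flag, and realized per-transition
retention counts are recorded, enabling parameter-recovery tests. All
randomness derives from one master seed through named substreams (genome,
lineage, methylome, expression), so stages regenerate independently.

What the generator does not emulate: CpG-island structure and local CpG
density variation, read-level noise and coverage heterogeneity,
chromatin-state context, overlapping or hierarchical TADs, and selection
on sequence. Passing tests therefore demonstrate the correctness and
calibration of the machinery under the stated generative assumptions, not
biological conclusions about real methylomes.

## Problem sizes and numerical choices in the test suite

Simulation-based checks run at desk scale with HMR density matched to the
generator defaults (about 20 basal HMRs per Mb, rising toward 50-90 per
Mb in leaves): one 6-Mb chromosome with 80 genes, 120 basal HMRs and 200
gains per transition. At that scale the suite verifies, among others:
type-I error of the empirical spatial test within 5% +/- 3% over 200
uniform-placement replicates (200 shuffle iterations each, with the
no-overlap shuffle so observed and null layouts follow the same placement
process and are exchangeable); at least 90% rejection on differentiated
leaves under default proximity bias; clustered-fraction monotonicity from
root to leaves in at least 95% of 100 lineages; and realized retention
inside the binomial 95% confidence band. The planted expression effect is
evaluated with 50-kb TADs and 200 regions per group — with 500-kb TADs on
the default genome nearly every TAD contains a cluster, so the contrast
saturates and detection is not identifiable there. Interval arithmetic is
checked against a per-basepair occupancy oracle on 1,000 random genomes
of up to 10 kb, cluster linking against a transitive-closure oracle up to
100 HMRs, and merging against GenomicRanges as an independent
cross-check.

## Known limitations

* The methylation matrix drops incomplete rows instead of imputing;
  with sparse tracks this can discard many consensus regions.
* The shuffle null preserves lengths and chromosome assignment but not
  local CpG density or GC content; a composition-matched null is out of
  scope.
* The literature-style `ranksum_means` spatial comparison is
  anti-conservative by construction and should be read descriptively; use
  the `empirical` mode for inference.
* Gene assignment requires final gene identifiers and replicate-averaged
  TPMs in the input tables; identifier conversion is out of scope.
* k-means group numbering is arbitrary (label sets, not group indices,
  are the stable output), and group naming is left to the user.
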