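# hmratlas

Comparative analysis of DNA hypomethylated region (HMR) patterns across
cell types and developmental stages.

## The scientific problem

Whole-genome bisulfite sequencing (WGBS) measures, for every CpG, the
fraction of reads carrying a methyl-C. Segmenting those fractions yields
hypomethylated regions — contiguous runs of lowly methylated CpGs, called
per cell type. Promoter HMRs are nearly invariant across cell types, but
non-coding HMRs mark putative enhancers whose presence, sharing and
spatial arrangement record a cell's developmental history: most HMRs of a
differentiated cell were established at earlier developmental stages and
persist, and newly established HMRs preferentially appear near existing
ones (within ~6 kb), building enhancer clusters associated with stronger
regulatory activity.

`hmratlas` implements that comparative layer as a tested, reusable
toolkit:

- **Non-coding filtering** — strand-aware promoter windows
  ([TSS − 2000, TSS + 1000) for `+` genes, mirrored for `−`) plus exons
  form an exclusion list; HMRs overlapping it by ≥ 1 bp or shorter than
  50 bp are removed.
- **Methylation matrix** — consensus regions (merged union of all cell
  types' HMRs) × cell types, holding mean per-CpG methylation; grouped by
  seeded k-means (k-means++/Lloyd, best of 10 restarts, k = 10 default)
  with groups labeled by cell types at ≤ 50% center methylation, and a
  Ward.D2 dendrogram of cell types.
- **Spacing statistics** — observed nearest-neighbor distances
  (`d(a,b) = max(0, max(start) − min(end))`, 0 when bookended) against a
  blacklist-aware shuffle null (lengths and chromosomes preserved,
  placement uniform over legal starts; iterations summarized by their
  mean), with both the literature's rank-sum comparison and a calibrated
  empirical permutation p-value.
- **Cluster annotation** — HMRs chained at end-to-end gaps ≤ 6 kb within
  one whitelist region (never crossing a TSS or exon); every HMR classed
  as cluster member (3+), pair member, unclustered, TSS/exon-proximal, or
  residual.
- **Lineage tracing** — per-stage origin sets (HMRs absent from all
  ancestors), direct and path-conditioned retention percentages,
  derivation labels (stem-derived / progenitor-derived / cell-specific /
  other) exported as annotation BEDs, and Sankey-style flow tables.
- **Gene assignment** — nearest expressed gene (TPM > 0) whose pairing
  with the region fits entirely inside one TAD, proportion-near-active
  curves at 10–150 kb thresholds with z-tests of proportions, and
  expression contrasts (two nearest genes, deduplicated, Wilcoxon
  rank-sum).
- **Annotation overlap** — per-state overlap fractions (ChromHMM-style),
  Euler counts over merged consensus units.
- **Synthetic lineages** — a generator for genomes, HMR lineages with
  known establishment/retention/proximity ground truth, bimodal
  methylomes and expression with planted effects, used to validate every
  stage.

See `vignettes/hmr-atlas-methods.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

Simulate a small developmental lineage (one 6-Mb chromosome, 120 basal
HMRs, 200 gains per transition, 35% proximity-biased), then filter,
classify, test spacing, and trace retention:

```r
library(hmratlas)

cfg <- sim_config(seed = 11, n_chrom = 1, chrom_len = 6e6, gene_count = 80,
                  basal_count = 120, gain_per_transition = 200)
genome  <- simulate_genome(cfg)
lineage <- simulate_lineage_hmrs(cfg, genome)
sapply(lineage$sets, nrow)
#>         H1       HSPC macrophage      Bcell
#>        120        306        474        484

filt <- filter_noncoding(lineage$sets$Bcell, genome$blacklist)
sc <- classify_hmrs(filt$hmrs, lineage$sets$Bcell, genome$blacklist,
                    genome$whitelist)
sc
#> Spatial classification (Bcell)
#> class
#> cluster_member    pair_member       residual    unclustered
#>            244             96             23            121

obs <- nearest_distances(filt$hmrs, quiet = TRUE)
nul <- shuffle_null(filt$hmrs, genome$blacklist, genome$sizes,
                    n_iter = 500, seed = 12, no_overlap = TRUE)
spatial_test(obs, nul, method = "empirical")
#> Spatial test (empirical): observed median 2598.0 bp vs expected 5628.8 bp, p = 0.01198

tr <- trace_lineage(lineage_order(lineage$sets, cfg$lineage))
tr[, c("origin_stage", "descendant", "n_origin", "n_overlap_path",
       "pct_path_string")]
#>   origin_stage descendant n_origin n_overlap_path pct_path_string
#> 1           H1       HSPC      120            108          90.00%
#> 2           H1 macrophage      120             95          79.17%
#> 3           H1      Bcell      120            101          84.17%
#> 4         HSPC macrophage      197            182          92.39%
#> 5         HSPC      Bcell      197            185          93.91%
```

Reading the output: half the differentiated cell's HMRs sit in clusters
of three or more; its HMRs lie far closer together (median 2.6 kb) than
uniformly re-placed ones (5.6 kb, empirical p ≈ 0.012); and most HMRs
established at the root or progenitor stage persist into the leaves —
retention tracks the generator's 0.9 per-transition probability, with
multi-step percentages compounding it.

A command-line wrapper with `filter`, `spatial-null`,
`annotate-clusters`, `trace`, `derive`, `simulate` and `run`
(end-to-end over a sample sheet) subcommands lives at
`inst/cli/hmr-atlas.R`.

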