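Package: hmratlas
Title: Comparative Analysis of DNA Hypomethylated Region Patterns Across Cell Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of hypomethylated regions (HMRs) called
    from whole-genome bisulfite sequencing across cell types and developmental
    stages. Builds promoter/exon exclusion lists and non-coding HMR sets, assembles
    consensus-region methylation matrices with k-means and Ward clustering, tests
    inter-HMR spacing against a blacklist-aware shuffle null, links HMRs into
    boundary-constrained clusters with a four-way spatial classification, traces
    HMR establishment and retention along developmental lineages, assigns HMRs to
    the nearest expressed gene within a topologically associated domain, computes
    overlap statistics against external annotations, and simulates developmental
    lineages of HMR sets with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), GenomicRanges, IRanges, jsonlite
Config/testthat/edition: 3
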