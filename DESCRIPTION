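Package: sccnv
Title: Single-Cell Copy Number Calling and Clonal Analysis for
    Low-Coverage Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting copy number variations (CNVs) from
    low-coverage single-cell whole-genome sequencing read positions:
    binning with a coverage-based bin-count rule, GC-content
    normalization by robust locally weighted regression, circular binary
    segmentation with a permutation-tested arc statistic, integer copy
    number assignment, per-cell quality metrics (MAPD, duplication rate,
    Lorenz-curve uniformity with Gini coefficient), simulation-based
    sensitivity and false-discovery benchmarking, sequencing-saturation
    analysis, and recovery of tumor clonal subpopulations across paired
    samples by Ward hierarchical clustering of segment ratios.  A
    synthetic-data module simulates clonal aneuploid genomes and noisy
    per-cell read sets (GC bias, overdispersion, PCR duplicates) so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
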