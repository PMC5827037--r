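Package: netscreen
Title: Differential Drug-Sensitivity Screening and Genomic Characterisation
    of Neuroendocrine Tumour Cell Lines
Version: 0.1.0
Authors@R:
    person("NET Screen", "Developers", email = "netscreen@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-dose inhibitor viability screens
    across groups of tumour cell lines: per-cell-line Z-score normalization
    of plate fluorescence intensities, group-difference selectivity
    statistics with empirical-null p-scores, target-class enrichment by
    Wilcoxon-Mann-Whitney rank tests with Benjamini-Hochberg false-discovery
    control, four-parameter logistic dose-response fitting, rule-based
    hard-filtering of called variants with filtering-funnel accounting and
    gene-level bi-allelic inactivation calls, and QC-dependent classification
    of array-CGH copy-number segments.  A synthetic-data module generates
    screens, dose-response series, variant tables and copy-number segments
    with known ground truth so that every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment
Config/testthat/edition: 3
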