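Package: pmca
Title: Permutation-Based Maximum Covariance Analysis for Cytological
    Deconvolution of Bulk Transcriptomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns genes in a bulk expression matrix to cytologically
    defined cell substages by maximum covariance analysis of paired
    substage-frequency and expression data, with permutation-calibrated
    selection of the pattern-matching window width. Includes combinatorial
    immunolabeling-based classification of meiotic germ cells into prophase
    substages, compositional frequency tables, expression preprocessing
    (detection filtering and log transformation), validation statistics
    (independent-PCA concordance, hypergeometric list enrichment), and a
    synthetic-data generator with planted substage-specific expression
    programs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, RNASeq, CellBiology,
    DimensionReduction, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
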