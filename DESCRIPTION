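Package: neuromirnet
Title: miRNA-mRNA Regulatory Network Analysis for Neuroinflammation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for building cell-type-specific miRNA-mRNA
    regulatory networks from paired small-RNA and mRNA sequencing cohorts.
    Provides negative-binomial differential expression (median-of-ratios
    normalization, moment-based dispersion estimation with trend shrinkage,
    Wald tests, Benjamini-Hochberg correction), cross-cohort consensus
    candidate selection, TargetScan-style prediction filtering stratified by
    cumulative weighted context++ score (CWCS), seed-match site scanning,
    bipartite network construction, hypergeometric overrepresentation
    analysis, and assay-level statistics (2^-ddCt quantification, real-time
    viability normalization, dual-luciferase RLU, EAE clinical-score AUC with
    Mann-Whitney U tests). A synthetic-data generator with ground-truth
    tables makes every stage verifiable without access to the original
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    SummarizedExperiment,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
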