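Package: countflow
Title: Provenance-Tracked Exploratory Analysis of RNA-Seq Count Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for exploratory analysis of bulk and
    single-cell RNA-seq count matrices. Provides a suite of normalization
    methods (median-of-ratios with a tunable inclusion criterion, trimmed
    mean of M-values, upper-quartile, spike-in based size factors,
    CPM/RPKM/TPM, quantile normalization), sample and feature quality
    control statistics and filters, nonparametric two-group differential
    expression with false discovery rate control, and regulatory-network
    influence scoring for ranking candidate trans-differentiation factors.
    Every derived dataset is tracked in a "data map": a directed acyclic
    derivation graph whose edges record the deriving operations, supporting
    automated re-analysis on node switch, lineage tables, report
    attachment, and whole-session archives that reproduce every result.
    Includes a synthetic count and network simulator so all statistical
    behaviour is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
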