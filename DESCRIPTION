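Package: netdifftest
Title: Differential Network Testing for Multivariate Biomedical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates weighted association networks from samples-by-variables
    data using Spearman correlation, distance correlation, or an EBIC-selected
    graphical lasso, and tests whether two networks differ by a paired or
    unpaired permutation test on ten network difference characteristics
    (global strength, Frobenius and maximum metrics, spectral and Jaccard
    distances, counts of edges, communities and isolated nodes, node degree
    and edge strength).  Also provides a matched case-control study pipeline
    (risk-set sampling, propensity-score and Mahalanobis matching with
    common-support and duplicate-control pruning, cross-sectional and
    longitudinal comparisons) and seeded generators for synthetic cohorts
    with prescribed Spearman correlation structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
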