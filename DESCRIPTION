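Package: degprune
Title: Density-Based Pruning and Ranking of Differentially Expressed Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pre-filters two-condition gene expression matrices by removing
    genes from the dense core of the (average expression, average difference)
    feature space, keeping sparse boundary genes as candidate differentially
    expressed genes (DEGs). Implements fixed-radius neighbour counting with a
    density threshold, a binary search for the radius that yields a desired
    candidate-list size, four classical DEG ranking statistics (fold change,
    rank product, pooled t-statistic, weighted average difference), a top-K
    evaluation harness (enrichment, true-DEG ranks, confusion labels, prefix
    ROC curves and unnormalised partial AUC), and a seeded synthetic-data
    generator with known true DEGs for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
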