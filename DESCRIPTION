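Package: cytofnet
Title: Phenotype Clustering and Correlation-Network Analysis for Mass
    Cytometry Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for case-control mass cytometry
    (CyTOF) studies: arcsinh transformation, batch-wise scale
    normalization and per-sample downsampling of cell-by-marker
    matrices; k-means phenotype-node clustering with elbow-based
    selection of the number of nodes and rule-based lineage gating;
    Wilcoxon rank-sum differential abundance of node frequencies; and
    cohort-wise signed correlation networks over panel-combined node
    frequencies with a comparative suite of graph properties (edge
    density, Freeman betweenness centralization, transitivity,
    modularity under greedy community detection, average path length,
    signed edge counts, per-lineage degree). Includes a Gaussian-copula
    synthetic-cohort generator with known ground truth so every stage is
    testable without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
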