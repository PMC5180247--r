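Package: ionomeNet
Title: Differential Correlation Network Analysis of Brain Ionome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-group, multi-time-point elemental
    (ionome) profiling data: Dixon's Q outlier screening with mean
    replacement, Kolmogorov-Smirnov/Lilliefors normality checks, Wilcoxon
    identification of differentially changed elements, hierarchical
    clustering and decision-tree classification of element profiles, and
    Spearman correlation networks with simulation-derived significance
    thresholds, differentially changed correlations (DCCs), group-specific
    edges and sign-reversed correlation changes. Includes a Gaussian-copula
    synthetic-data generator that emulates a three-group rodent brain
    ionome study design, and Cytoscape-compatible SIF/GraphML export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml,
    jsonlite,
    nortest,
    rpart,
    e1071,
    randomForest,
    igraph,
    ape,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
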