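Package: omicsml
Title: Automated, Explainable Machine Learning for Omics and Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, configuration-driven machine-learning workflow for
    omics feature tables (gene-expression counts, microbiome abundances, SNP
    genotype dosages, metabolite intensities) and generic numeric tabular data.
    Provides omic-aware filtering and normalisation (including trimmed mean of
    M-values for raw counts), train/test splitting with quantile
    standardisation fitted on the training partition only, univariate feature
    selection with an automated search for the number of features, optional
    class rebalancing, cross-validated hyperparameter tuning over a registry of
    classical learners, a geometric train/test rule for recommending the best
    model, and model explanations via permutation importance and exact
    tree-path Shapley attributions, exported as tidy tables and plots.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    Rcpp,
    readr,
    stats,
    stringr,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
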