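Package: qsarkit
Title: QSAR Modelling Toolkit for Kinase Inhibitor Potency Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantitative structure-activity relationship
    (QSAR) modelling of kinase inhibitor potency (pIC50), built around
    epsilon support vector regression. Provides compound and activity
    table input, molecular descriptor and fingerprint generation through
    OpenBabel, ingestion of docking-energy descriptor tables, a
    three-stage feature selection procedure (degenerate-column removal,
    pairwise-correlation pruning, correlation-based subset selection and
    remove-one backward elimination under a feature budget),
    cross-validated model training and evaluation (R, R-squared, MAE,
    RMSE), fragment class-frequency enrichment analysis, cross-class
    prediction protocols, and a synthetic two-scaffold compound
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
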