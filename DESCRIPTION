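Package: gaclock
Title: Gestational Age Clocks from Cord Blood DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating epigenetic gestational age
    clocks from methylation array beta values. Simulates cord-blood cohorts
    with a sparse set of gestational-age-predictive CpGs, filters probes
    (cross-reactive, detection p-value, SNP-overlapping, non-autosomal),
    trains L1-penalised (Lasso) clocks by coordinate descent with K-fold
    cross-validation, applies clocks from coefficient files, scores
    predictions with MM-type robust regression (robust R-squared, residual
    scale, median absolute deviation), compares clocks with a paired
    percentile bootstrap, derives gestational age from assisted-reproduction
    procedure dates (embryo-transfer-date estimates), and tests gestational
    age acceleration against ART status by logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
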