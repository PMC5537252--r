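Package: phosforest
Title: Kinase-Specific Phosphorylation Site Prediction with Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable framework for kinase-specific phosphorylation
    substrate and site prediction. Encodes 9-mer peptide windows together
    with predicted secondary structure, solvent accessibility and intrinsic
    disorder as binary feature blocks, identifies over- and
    under-represented functional annotation terms by two-sided
    hypergeometric tests with Bonferroni correction, scores proteins by a
    log-odds functional score, ranks features by minimum-redundancy
    maximum-relevance (mRMR) mutual information, and trains random-forest
    classifiers evaluated by repeated stratified cross-validation with
    specificity-calibrated score thresholds. Ships a synthetic
    planted-motif data generator so the whole pipeline is exercisable and
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    randomForest,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
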