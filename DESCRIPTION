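Package: rpinet
Title: Sequence-Based Prediction of RNA-Protein Interactions and
    Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether an RNA and a protein interact using only
    their sequences. Proteins are encoded as normalized conjoint-triad
    frequencies over a 7-letter reduced amino-acid alphabet (343
    features) and RNAs as normalized 4-mer frequencies (256 features);
    the concatenated 599-feature pair vector is classified with a random
    forest or a support vector machine using a normalized polynomial
    kernel of order 2 with Platt-calibrated probabilities. Includes
    benchmark dataset construction (length filtering, 30 percent
    identity pair de-redundancy, balanced negative sampling with
    similarity exclusion), stratified cross-validation with ROC/AUC,
    bipartite interaction-network prediction and export, a synthetic
    planted-signal data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    kernlab,
    methods,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
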