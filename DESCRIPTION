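Package: phytoscreen
Title: Structure-Based Screening of Food Compounds for Protein-Target
    Bioactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Ligand-based virtual screening of food compounds against a
    protein target. Builds a random-forest classifier from drug bioactivity
    records (IC50/EC50-filtered positives, Tanimoto-filtered random
    negatives), represents molecules as 1024-bit path-based binary
    fingerprints computed from a built-in SMILES parser, and scores a food
    compound library for putative bioactivity, reporting scored compounds
    with source foods, amounts, and novelty status. Includes a synthetic
    fixture generator with a planted structure-activity signal so the full
    pipeline is testable without external databases.
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
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    DBI,
    RSQLite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
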