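Package: ddganchor
Title: Anchor-Query Pairwise Learning for Mutation-Induced Binding Free
    Energy Changes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarking pipeline for predicting mutation-induced changes in
    protein-ligand binding free energy (ddG, kcal/mol) from sequence-derived
    features. Provides embedding-difference featurization of wild-type and
    mutant proteins joined with ligand fingerprints, leakage-aware dataset
    partitioning (random 8:1:1 and UniProt-grouped), train/test similarity
    diagnostics, an anchor-query pairwise learning framework with dddG
    regression targets and ensemble recovery of per-query ddG, regression
    metrics and resistance classification at the 10-fold IC50 threshold, a
    repeat harness for mean +/- SD reporting, and a synthetic-data generator
    that reproduces the group-level distribution shift which makes random
    splits look optimistic and grouped splits collapse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Biostrings,
    ChemmineOB,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
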