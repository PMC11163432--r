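Package: ligscreen
Title: Fingerprint-Driven Virtual Ligand Screening with Pocket-Aware
    Boosted Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Toolkit for ligand-based and pocket-informed virtual ligand
    screening. Computes substructure-key, linear-path (FP2-style) and
    extended-connectivity (Morgan/ECFP4) bit fingerprints with documented
    hashing and folding conventions; derives binding-pocket amino-acid
    composition features from template-pocket metadata; trains
    gradient-boosted regression models that score candidate ligands
    against a target; screens compound libraries by Tanimoto similarity
    to template ligands; calibrates raw method scores to predicted
    precision by isotonic regression and combines methods by best
    predicted precision; and evaluates ranked screens with enrichment
    factors, ROC enrichment and the area under the precision-recall
    curve. Ships a synthetic multi-target actives/decoys benchmark
    generator with a planted scaffold signal so the whole pipeline can be
    exercised end to end without external downloads.
License: MIT + file LICENSE
Imports:
    Biostrings,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
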