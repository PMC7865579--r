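Package: gliomaTP
Title: Ensemble Transcriptomic Classification of Gliomas from Single-Molecule
    Count Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying gliomas into four
    transcriptome profiles (TP1, TP2a, TP2b, TP3) from NanoString
    nCounter-style single-molecule count data. Implements RCC lane parsing and
    quality control, two-stage geometric-mean normalization (positive spike-in
    controls then housekeeping genes), z-score standardization with
    empirical-Bayes location/scale batch integration against a reference
    expression compendium, an ensemble of 1000 linear support-vector
    classifiers built by stratified gene-group subsampling and recursive
    feature elimination with plurality voting and confidence-based abstention,
    and Kaplan-Meier / Cox proportional-hazards comparison of TP1 versus
    non-TP1 survival. A synthetic-data module generates reference compendia,
    RCC lanes with batch and lane effects, technical replicates, and survival
    tables with known ground truth so every stage is testable without
    restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    sva,
    mclust,
    withr,
    optparse
biocViews: Classification, GeneExpression, Normalization, BatchEffect,
    Survival, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
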