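Package: miconet
Title: Weighted Co-Occurrence Network Analysis of 16S Microbiome Compositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for community-level analysis of 16S rRNA gene survey data.
    Implements retain-resolve taxon agglomeration (common amplicon sequence
    variants kept as-is, rare ones collapsed to filtered genus-level taxa with
    an "Other taxa" remainder preserving the compositional closure), centered
    log-ratio transformation with empirical-Bayes-moderated covariate
    adjustment, weighted taxon correlation networks built on the topological
    overlap measure with soft-threshold selection and module detection, module
    eigentaxon / module membership / hub-taxon statistics, bootstrap Jaccard
    module-stability validation, Dirichlet Monte-Carlo per-taxon linear models
    and random-forest importance ranking, and a consensus rule combining the
    three methods to nominate trait-associated taxa. A synthetic-data
    generator with planted co-occurrence modules, trait associations and
    covariate confounding makes every stage testable without access to
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    randomForest,
    stats,
    utils,
    vegan
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
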