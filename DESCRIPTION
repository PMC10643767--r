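Package: primateClocks
Title: Multi-Species Methylation Age Clocks, EWAS Meta-Analysis and Sex
    Prediction for Primate Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and cross-validates penalized-regression DNA methylation
    age clocks across primate species, with the age transformations used for
    multi-species clocks (identity, square root with offset, log-linear,
    relative age), species-balanced cross-validation, epigenetic age
    acceleration, a two-stage unweighted Stouffer meta-analysis of per-stratum
    correlation EWAS of age, stratified and pooled EWAS of sex with consensus
    calling of sex-associated methylation positions, an elastic-net sex
    predictor, and gene-region enrichment of top CpG sets. Includes a
    synthetic-cohort generator that emulates the statistical structure of
    multi-species, multi-tissue methylation array data so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    data.table,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'ageTransforms.R'
    'simulateCohort.R'
    'clock.R'
    'clockIO.R'
    'crossValidation.R'
    'ewasAge.R'
    'sexAnalysis.R'
    'enrichment.R'
    'cohortIO.R'
    'utils.R'
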