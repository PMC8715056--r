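Package: codecomp
Title: Codecomposition of Hippocampus-Default Network Structural Covariation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Doubly multivariate analysis of structural covariation between
    hippocampal subfield volumes and default-network parcel volumes.
    Implements nuisance deconfounding, two-block canonical correlation
    analysis (CCA) with a deterministic sign convention, a bootstrap
    group-difference test with mode matching (order and sign alignment via
    optimal assignment) and 10/90 percent percentile-interval hit detection,
    an additive polygenic-score engine with summary-statistic quality
    control and p-value thresholding, and a Bayesian logistic regression
    linking polygenic-score extremes to per-participant mode expressions.
    A synthetic cohort generator with planted latent modes, group-specific
    loading shifts, confound couplings, and sparse SNP effects provides
    recoverable ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    rjags,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
biocViews: StatisticalMethod, DimensionReduction, Regression, Bayesian
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'atlas.R'
    'bayes.R'
    'cca.R'
    'contrast.R'
    'deconfound.R'
    'io.R'
    'pipeline.R'
    'prs.R'
    'regression.R'
    'synthetic-cohort.R'
    'utils-internal.R'
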