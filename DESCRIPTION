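Package: psfdilution
Title: Plant-Soil Feedback, Pathogen Dilution and Biodiversity Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking soil pathogen community dissimilarity to pairwise
    plant-soil feedback (PSF), plot-level predicted PSF and pathogen dilution,
    and biodiversity effects (complementarity, selection, relative yield
    total).  Includes a greenhouse PSF estimator with delta-method variances
    and random-effects meta-analysis, an exhaustive AICc model-selection and
    model-averaging fit of the dissimilarity-to-PSF predictor, the
    Loreau-Hector additive partition of net biodiversity effects, a
    frequency-dependent (replicator) feedback model with Cramer-rule
    feasibility, Jacobian stability and community-level feedback screening of
    all multispecies communities assembled from a species pool, and a seeded
    synthetic-data generator that reproduces the experimental design of a
    prairie biodiversity experiment (240 field plots, 702 greenhouse pots, 81
    pairwise feedback tests) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vegan,
    metafor,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
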