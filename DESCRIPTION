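Package: parashift
Title: Host-Conditioned Species Distribution Modelling and Climate-Change
    Range Shift Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for hierarchical host-parasite species distribution
    modelling under climate change. Fits presence/background maximum-entropy
    niche models (an L1-penalized Gibbs formulation over linear, quadratic,
    product and hinge features), screens bioclimatic predictors for
    collinearity, injects modelled host suitability as a biotic predictor for
    a parasite, projects suitability under SSP x GCM scenario ensembles, and
    classifies per-cell range change (persistence, expansion, contraction,
    still-unsuitable) with percentage accounting. Includes a synthetic-world
    generator (autocorrelated climate fields, known logistic niches, biased
    occurrence sampling, additive scenario shifts) so the whole pipeline can
    be exercised and validated against known ground truth without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
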