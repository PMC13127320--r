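Package: adaptbias
Title: Automation-Bias Analysis for AI-Propagated Target Volumes in Adaptive Radiotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify whether physicians supervising algorithm-propagated
    clinical target volumes (CTVs) in online adaptive radiotherapy inherit the
    propagation algorithm's errors. Provides mm-aware morphology and surface-distance
    computations on binary structure masks (expansion/contraction via anisotropic
    Euclidean distance transforms, mean distance to agreement, signed directional
    deviations, octant classification, surface-patch areas), the test-segment
    identification recipe built from rim/contraction Boolean operations, STAPLE
    expectation-maximization consensus over multiple readers, inter-shell volume
    extraction with generalized equivalent uniform dose (gEUD) summaries, the full
    cross-over trial statistics (exact binomial superiority test and power,
    Clopper-Pearson intervals, Fisher subgroup tests, a mixed linear model of
    adjusted on unadjusted signed deviations with physician-specific slopes, a
    location-adjusted k-sample Ansari-Bradley scale test, and a carryover-balanced
    cross-over schedule generator), and a synthetic-cohort generator that emulates
    the study design end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
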