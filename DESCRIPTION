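Package: catspredict
Title: Trait-Based Prediction of Community Assembly by Trait Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibrates community-weighted mean (CWM) trait-environment
    relationships from vegetation survey data using smooth additive models,
    predicts CWM trait values for new environments, and solves the Community
    Assembly by Trait Selection (CATS) maximum-entropy model to predict
    species relative abundances under those CWM constraints. Includes
    permutation-based goodness-of-fit statistics (R-squared on relative
    abundances and RMSE on square-root transformed abundances), two-way
    permutation MANOVA on Bray-Curtis or Euclidean distances, and a
    synthetic-data generator that emulates trait-filtered landscapes and
    factorial sowing experiments for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    vegan,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
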