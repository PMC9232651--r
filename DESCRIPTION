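Package: kalmag
Title: Bayesian Observer Models for Magnitude Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing central tendency and sequential dependence in
    magnitude reproduction experiments (duration, distance, angle) with a family
    of Bayesian observer models: a static observer that assumes independently
    drawn stimuli, a simple iterative observer that assumes a random-walk
    stimulus sequence, and a two-state observer that assumes stimuli drawn
    around a drifting mean. All three are expressed as one discrete Kalman
    filter operating in Weber-Fechner log space. The package generates
    stimulus sequences under each generative assumption (including
    histogram-matched sequences), simulates observers, computes trial-level
    bias metrics (central tendency, serial dependence, partial and lagged
    correlations), fits models by linear-domain least squares with
    confidence intervals, selects among nested models by windowed
    leave-one-out cross-validation for time series, and predicts held-out
    conditions from fitted parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
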