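Package: sctrnn
Title: Stochastic Continuous-Time Recurrent Networks with Parametric Bias
    for Simulating Behavioral Rigidity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a stochastic continuous-time recurrent neural
    network (S-CTRNN) with parametric bias (PB) units that learns
    visuo-proprioceptive behavior sequences by heteroscedastic
    negative-log-likelihood minimization, adapts its intention (PB state)
    online by precision-weighted prediction-error regression over a
    sliding window, and exhibits behavioral rigidity (freezing,
    inappropriate repetition) when the estimated sensory variance is
    artificially scaled. Includes a synthetic ball-interaction
    environment with four quasi-periodic behaviors, a KL-divergence
    histogram classifier of generated movement, and a repeated-measures
    experiment grid over precision manipulations with ANOVA and
    Holm-Bonferroni summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils,
    cluster
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(load = "source")
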