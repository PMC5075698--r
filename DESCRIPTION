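Package: jmbench
Title: Simulation Benchmark of Joint Models Against Cox Regression with a
    Time-Dependent Predictor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to simulate time-to-event outcomes driven by a latent
    linear mixed-effects trajectory, and to compare estimation strategies
    for the effect of a time-dependent predictor on the hazard:
    baseline-value-only Cox regression, last-observation-carried-forward
    time-dependent Cox regression, and maximum-likelihood shared
    random-effects joint models with Weibull or piecewise-constant
    baseline hazards (Gauss-Hermite quadrature). Includes a replicate
    evaluation harness reporting confidence-interval coverage and the
    percentage of estimates below the true value, and a stage for
    counting-process cohort data in the format of ultra-high-risk
    transition-to-psychosis studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    lme4,
    jsonlite,
    withr
Config/testthat/edition: 3
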