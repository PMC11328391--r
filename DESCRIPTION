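Package: spillroc
Title: Arm-Based Diagnosis of Spillover in Infection-Prevention Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for visualizing and diagnosing spillover (interference between
    randomized arms, a SUTVA violation) within collections of randomized concurrent
    controlled trials of infection-prevention interventions. Provides arm-level
    random-effects meta-analysis of logit-transformed incidence proportions with
    heterogeneity statistics and prediction intervals, a bivariate binomial-normal
    random-effects model fitted by adaptive Gauss-Hermite quadrature with SROC
    curves and confidence/prediction ellipses, a spillover count-perturbation
    simulation engine, a three-comparator dispersion diagnosis, and a synthetic
    trial-cohort generator so the full analysis runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    lme4,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
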