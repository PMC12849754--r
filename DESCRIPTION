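Package: ahadjust
Title: Confounding-Adjusted Inference for the Average Hazard of Censored
    Time-to-Event Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point estimation and bootstrap confidence intervals for the
    average hazard (cumulative incidence at a truncation time divided by the
    restricted mean survival time), its group difference (DAH) and ratio
    (RAH), from right-censored observational data. Seven survival-curve
    adjustment methods are provided: unadjusted Kaplan-Meier, direct
    standardization via a Cox model (G-formula), inverse probability of
    treatment weighted Kaplan-Meier and cumulative-hazard estimators,
    bidirectional propensity-score matching, empirical-likelihood covariate
    balancing, and augmented IPTW with inverse probability of censoring
    weights. A simulation engine generates data under configurable
    scenarios, computes oracle true values by counterfactual Monte Carlo,
    and summarizes estimator performance (relative bias, root mean squared
    error, coverage, confidence-interval width).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
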