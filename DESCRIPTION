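Package: csAUC
Title: Time-Dependent Cause-Specific AUC for Right-Censored Data with
    Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Nonparametric estimation of the incident/dynamic cause-specific
    time-dependent AUC(t) of a baseline marker for right-censored survival
    times with competing risks.  Provides a local estimator (cause-specific
    weighted mean rank, cWMR) based on nearest-neighbour smoothing of observed
    rank AUCs with leave-one-out cross-validated bandwidth selection and a
    normal-approximation variance, and a global estimator (cause-specific
    fractional polynomial likelihood, cFPL) that models logit AUC(t) with
    fractional polynomials of time fitted by a binomial partial likelihood
    with a pairwise sandwich covariance.  Includes exact truth oracles for
    bivariate-normal and mixture marker-time laws, a competing-risks data
    simulator, and a Monte-Carlo/bootstrap study driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
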