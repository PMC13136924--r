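Package: dicph
Title: Proportional Hazards Regression with an Interval-Censored Outcome
    and an Interval-Censored Covariate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semiparametric proportional hazards regression when both the
    outcome event time and a covariate event time are interval-censored by
    intermittent monitoring, as in HIV viral suppression/rebound episodes.
    Both baseline cumulative hazards are estimated nonparametrically as
    step functions with jumps at the pooled bracket endpoints, and the
    nonparametric maximum likelihood estimator is computed by an EM
    algorithm based on latent Poisson counts, with closed-form baseline
    updates in the M-step. Inference uses the observed information matrix,
    and clustered episodes (repeated suppression-rebound cycles within a
    participant) are handled by an independence composite likelihood with
    sandwich or cluster-bootstrap variance estimation.  Includes simulators
    for monitoring schedules, Weibull and piecewise proportional-hazards
    event times and Gaussian-copula clustered episodes, midpoint-imputation
    comparator fits, and drivers that aggregate bias, empirical and
    model-based standard errors and confidence-interval coverage over
    replicated simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    survival,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
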