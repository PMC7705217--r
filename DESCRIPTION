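Package: ropebest
Title: Robust Bayesian Estimation of Pre/Post Change with ROPE Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying pre/post change in questionnaire data
    across diagnostic groups with robust Bayesian estimation.  Models
    individual change scores with t-distributed noise (normality parameter
    nu under an exponential prior), fits single-group, two-group,
    ANOVA-like multi-group and regression models via JAGS, and turns the
    posterior draws into highest-density intervals, standardized effect
    sizes and region-of-practical-equivalence (ROPE) decisions.  Includes
    questionnaire scoring and reliability (Cronbach's alpha, KR-20),
    descriptive frequency tables with explicit denominators, MCMC
    convergence diagnostics with an automatic nu-floor remediation policy,
    a seeded synthetic cohort generator with known ground truth, and a
    config-driven pipeline that emits report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    rjags,
    jsonlite,
    stats,
    utils
Suggests:
    coda,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
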