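Package: rtscale
Title: Location-Scale Modeling of Survey Response-Time Paradata
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for inferring cognitive abilities from survey response-time
    (RT) paradata. Implements RT preprocessing (item eligibility filters,
    percentile trimming, log transformation), estimation of item time
    intensities via a cross-classified random-effects model, Bayesian
    estimation of multilevel location-scale models with random log residual
    variance (including an expanded model with a random slope on item time
    intensity), extraction of empirical-Bayes person-level RT components, and
    cross-sectional and time-lagged regressions linking those components to
    cognitive test scores with cluster-robust standard errors. A synthetic
    panel generator with known ground truth supports validation of every
    stage at desk scale.
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
    MASS,
    lme4,
    pracma,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr,
    optparse
Config/testthat/edition: 3
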