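Package: ucate
Title: Individual-Specific Causal Effects from N-of-1 Trials by G-Computation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the causal analysis of single-participant (N-of-1)
    crossover trials with time-varying confounding and mediation. Builds the
    fixed 8-hourly measurement calendar of a month-long alcohol-abstinence
    trial, fits the three stationary conditional models of the assumed data
    generating process (logistic regression for social interaction,
    zero-inflated Poisson regression for alcohol units, proportional-odds
    ordinal regression for mood), estimates the per-time-point
    individual-specific conditional average treatment effect (U-CATE) of
    abstinence on mood by a g-computation Monte Carlo algorithm, and attaches
    parametric-bootstrap standard errors with normal-approximation confidence
    intervals. A synthetic-trial generator with published coefficient values
    as defaults makes the full pipeline testable without access to the
    original private dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    withr
Config/testthat/edition: 3
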