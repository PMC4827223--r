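Package: covadj
Title: Covariate Adjustment Methods for Randomised Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits randomised-trial outcome models that adjust for a continuous
    baseline covariate in seven ways (median dichotomisation, quartile
    categorisation, linear, first- and second-order fractional polynomials,
    and restricted cubic splines with 3 or 5 knots), for continuous (least
    squares) and binary (logistic) outcomes, with Wald inference on the
    treatment effect.  Includes a synthetic-trial generator with a
    latent-logistic model for binary outcomes, closed-form and
    simulation-based effect-size calibration, and a Monte-Carlo engine that
    estimates bias, log-odds-ratio attenuation, type I error and power of
    each adjustment method, together with command-style front ends for
    simulation grids and for analysing user-supplied trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
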