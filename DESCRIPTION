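Package: lmmborrow
Title: Dynamic Borrowing of Historical Controls in Bayesian Linear Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian dynamic borrowing of a historical control arm in
    longitudinal two-arm clinical trials analysed with the constrained
    longitudinal data analysis (cLDA) linear mixed model. Implements the
    modified power prior in its conditional and marginal forms, with
    path-sampling (thermodynamic integration) estimation of the power-prior
    scaling constant on a grid and linear interpolation for continuous-power
    sampling; the commensurate prior; and pooling and no-borrowing baselines.
    Includes a trial simulator with study-level random effects for
    between-study heterogeneity and a replication harness computing operating
    characteristics (type I error, power, calibrated power, bias, posterior
    SD, MSE, with Monte Carlo standard errors and McNemar paired tests).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    coda,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
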