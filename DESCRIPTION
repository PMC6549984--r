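Package: lpmbin
Title: Linear-in-Probability Models for Binary Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimation and diagnostics for the linear-in-probability model
    for binary outcomes coded {-1, +1}, in which pr(Y = y | x) =
    (1 + y * b'x) / 2 so that E(Y | x) = b'x.  Provides ordinary
    least-squares estimation with a heteroskedasticity-corrected covariance
    matrix, a one-step weighted least-squares variant, constrained maximum
    likelihood on the bounded parameter space, an analytic comparison of the
    OLS and maximum-likelihood variances, an out-of-range fitted-value
    diagnostic based on bivariate-normal quadrant probabilities, coefficient
    interpretation in expected-count units with a logistic-regression
    coefficient-ratio comparison, a factorial extreme-assignment sensitivity
    analysis for missing covariates, a synthetic-data generator for the
    model, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
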