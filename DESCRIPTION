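Package: stmnd
Title: Integral, Mean and Covariance of Simplex-Truncated Multivariate
    Normal Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the normalising integral, mean vector and covariance
    matrix of a multivariate normal distribution truncated to the
    non-negative region under the unit simplex, the natural distribution for
    compositional data that would otherwise be normally distributed. Three
    cross-validating routes are provided: naive rejection sampling; a
    rejection-free route combining elliptical slice sampling under linear
    constraints with subset simulation and the Holmes-Diaconis-Ross
    estimator; and a deterministic semi-analytical route based on the
    inclusion-exclusion principle and moments of hyperrectangularly
    truncated Gaussians. Includes a benchmark-problem generator, a
    deterministic quadrature oracle for low dimensions, and tidy accessors
    for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    pracma,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
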