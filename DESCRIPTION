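Package: evolvavg
Title: Quasi-Exact Average Evolvability Measures for G Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Evaluates average measures of evolvability, constraint and
    matrix comparison for additive genetic covariance (G) matrices under
    selection gradients distributed uniformly on the unit hypersphere.
    Average conditional evolvability, autonomy, respondability, flexibility,
    response difference and response correlation are moments of (multiple)
    ratios of quadratic forms in normal variables; they are computed
    quasi-exactly as truncated infinite series in top-order zonal and
    invariant polynomials of matrix arguments, with hard truncation-error
    bounds where available. Also provides the corresponding fixed-gradient
    measures with generalized-inverse handling of singular G, Monte Carlo
    ("random skewers") estimation, eigenvalue-based delta-method
    approximations, test-matrix generators (eigenvalue conformations and
    Givens-rotation correlation matrices), and a general moment engine for
    ratios of quadratic forms in normal variables with nonzero mean.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
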