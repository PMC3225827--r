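Package: tauleapRK
Title: Runge-Kutta Tau-Leap Methods with Extended Stability for
    Stochastic Chemical Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of well-stirred reaction networks with
    the exact stochastic simulation algorithm (SSA), the Poisson tau-leap
    method, and a general class of explicit s-stage Runge-Kutta tau-leap
    methods that reuse a single set of Poisson draws per step.  Provides
    the linear stability and stationary-variance theory for these methods
    (stability function R(z), relative variance psi(z), stability and
    variance-bounded intervals, matrix mean propagators), and a
    deterministic optimizer that derives stability-maximal method
    coefficients under a bound on the stationary relative variance.
    Includes analytically tractable reference systems (reversible
    isomerisation, the Schlogl reaction) and ensemble summary statistics
    (moments, relative variance estimates, Kullback-Leibler divergence,
    failure rates).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    parallel,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
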