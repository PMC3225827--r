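#' Butcher tableau of a Runge-Kutta method
#'
#' An s-stage Runge-Kutta method is characterised by its Butcher tableau
#' `(A, b, w)`: the `s x s` stage matrix `A` (entries `alpha_ij`), the
#' weight vector `b` (entries `beta_j`), and the abscissae `w = A e`.
#' A method is *explicit* when `A` is strictly lower triangular.  Methods
#' used for tau-leap simulation must satisfy `sum(b) = 1` (the first
#' stability coefficient `r_1 = b'e = 1`), which makes the leap update
#' consistent with the Poisson tau-leap drift.
#'
#' @param A `s x s` numeric matrix (a scalar is accepted for `s = 1`).
#' @param b numeric weight vector of length `s`.
#' @param w optional abscissae; defaults to `A %*% e` and a mismatch is an
#'   error.
#' @return Object of class `"butcher_tableau"` with fields `s`, `A`, `b`,
#'   `w`, `explicit`.
#' @examples
#' tableau_preset("gillespie-midpoint")
#' @export
butcher_tableau <- function(A, b, w = NULL) {
  A <- as.matrix(A)
  s <- length(b)
  stopifnot(nrow(A) == s, ncol(A) == s, is.numeric(A), is.numeric(b))
  we <- as.numeric(A %*% rep(1, s))
  if (is.null(w)) w <- we
  else if (max(abs(w - we)) > 1e-12)
    stop("abscissae w must equal A %*% e")
  explicit <- all(A[upper.tri(A, diag = TRUE)] == 0)
  structure(list(s = s, A = unname(A), b = as.numeric(b),
                 w = as.numeric(w), explicit = explicit),
            class = "butcher_tableau")
}

#' @export
print.butcher_tableau <- function(x, ...) {
  cat("<butcher_tableau> s =", x$s,
      if (x$explicit) "(explicit)" else "(implicit)", "\n")
  tab <- cbind(format(x$w, digits = 6), format(x$A, digits = 6))
  for (i in seq_len(x$s)) cat(" ", tab[i, 1], "|", tab[i, -1], "\n")
  cat("  ", strrep("-", 8), "+", "\n")
  cat("        |", format(x$b, digits = 6), "\n")
  invisible(x)
}

#' Stability polynomial coefficients
#'
#' Coefficients `(r_1, ..., r_s)` of the polynomial stability function
#' `R(z) = 1 + sum_j r_j z^j` of an explicit Runge-Kutta method.
#' Variance-bounded tau-leap families fix `r_1 = 1`.
#'
#' @param r numeric coefficient vector `(r_1, ..., r_s)`.
#' @return Object of class `"stability_polynomial"`.
#' @export
stability_polynomial <- function(r) {
  stopifnot(is.numeric(r), length(r) >= 1)
  structure(list(r = as.numeric(r)), class = "stability_polynomial")
}

#' @export
print.stability_polynomial <- function(x, ...) {
  cat("<stability_polynomial> R(z) = 1 +",
      paste(sprintf("%.6g z^%d", x$r, seq_along(x$r)), collapse = " + "),
      "\n")
  invisible(x)
}

#' Built-in tableau presets
#'
#' Returns named Butcher tableaus:
#' * `"poisson"`: the Poisson tau-leap method (`s = 1`, `A = 0`,
#'   `beta_1 = 1`), with `R(z) = 1 + z`.
#' * `"gillespie-midpoint"`: the explicit midpoint tau-leap (`s = 2`,
#'   `b = (0, 1)`, `alpha_21 = 0.5`), `R(z) = 1 + z + z^2/2`.
#' * `"implicit-midpoint"`: `A = 1/2`, `b = 1`; `R(z) =
#'   (1 + z/2)/(1 - z/2)` and relative variance identically 1.  Supported
#'   by the analysis operations only — the simulators reject implicit
#'   tableaus.
#' * `"rk-tauleap-s{S}-eps{E}"` for `S` in 3, 5 and `E` in 0.1, 0.25,
#'   0.5: variance-bounded stability-maximal methods shipped with the
#'   package (regenerated by `tools/make_tableaus.R` via
#'   [optimize_polynomial()]), in efficient subdiagonal form.
#'
#' @param name preset name, e.g. `"poisson"` or `"rk-tauleap-s3-eps0.1"`.
#' @return A [butcher_tableau()].
#' @export
tableau_preset <- function(name) {
  switch(name,
    "poisson" = butcher_tableau(matrix(0, 1, 1), b = 1),
    "gillespie-midpoint" =
      butcher_tableau(matrix(c(0, 0.5, 0, 0), 2, 2), b = c(0, 1)),
    "implicit-midpoint" = butcher_tableau(matrix(0.5, 1, 1), b = 1),
    {
      m <- regmatches(name,
        regexec("^rk-tauleap-s([0-9]+)-eps([0-9.]+)$", name))[[1]]
      if (!length(m)) stop("unknown tableau preset: ", name)
      path <- system.file("extdata", "tableaus",
        paste0("rk-tauleap-s", m[2], "-eps", m[3], ".yaml"),
        package = "tauleapRK")
      if (path == "") stop("no shipped coefficients for preset: ", name)
      read_optimization_result(path)$tableau
    })
}

#' Stability function R(z)
#'
#' Evaluates `R(z) = 1 + z b' (I - A z)^{-1} e`, the amplification factor
#' of the Runge-Kutta method on the scalar linear test problem
#' `y' = lambda y` with `z = h lambda`.  For explicit tableaus this is a
#' polynomial of degree at most `s`; for implicit tableaus it is a
#' rational function and has poles where `I - A z` is singular.
#'
#' @param tab a [butcher_tableau()].
#' @param z real or complex scalar (or vector, evaluated elementwise).
#' @return `R(z)`, same scalar kind as `z`.
#' @examples
#' stability_function(tableau_preset("poisson"), -1)          # 0
#' stability_function(tableau_preset("implicit-midpoint"), -2) # 0
#' @export
stability_function <- function(tab, z) {
  stopifnot(inherits(tab, "butcher_tableau"))
  if (length(z) > 1) return(vapply(z, function(zi)
    stability_function(tab, zi), if (is.complex(z)) complex(1) else numeric(1)))
  s <- tab$s
  e <- rep(1, s)
  M <- diag(s) - tab$A * z
  y <- tryCatch(solve(M, e), error = function(err)
    stop("stability function singular at z = ", format(z)))
  1 + z * sum(tab$b * y)
}

#' Stability polynomial of an explicit tableau
#'
#' Computes the coefficients `r_j = b' A^{j-1} e` of the polynomial form
#' `R(z) = 1 + sum_j r_j z^j` of an explicit method's stability function,
#' with trailing zero coefficients trimmed.
#'
#' @param tab an explicit [butcher_tableau()].
#' @return A [stability_polynomial()].
#' @export
stability_polynomial_from_tableau <- function(tab) {
  stopifnot(inherits(tab, "butcher_tableau"))
  if (!tab$explicit)
    stop("stability function is rational, not polynomial (implicit tableau)")
  s <- tab$s
  v <- rep(1, s)              # A^{j-1} e accumulated
  r <- numeric(s)
  for (j in seq_len(s)) {
    r[j] <- sum(tab$b * v)
    v <- as.numeric(tab$A %*% v)
  }
  while (length(r) > 1 && abs(r[length(r)]) < 1e-14) r <- r[-length(r)]
  stability_polynomial(r)
}

# Normalise the various method descriptions to an R(z) evaluator.
as_R_evaluator <- function(obj) {
  if (inherits(obj, "butcher_tableau"))
    return(function(z) stability_function(obj, z))
  if (inherits(obj, "stability_polynomial")) {
    r <- obj$r
    return(function(z) {
      R <- 1 + 0 * z
      zp <- 1 + 0 * z
      for (j in seq_along(r)) { zp <- zp * z; R <- R + r[j] * zp }
      R
    })
  }
  if (is.function(obj)) return(obj)
  stop("expected a butcher_tableau, stability_polynomial or function")
}

#' Relative stationary variance psi(z)
#'
#' For a method with stability function `R`, the stationary variance on
#' the reversible isomerisation test system is `psi(z)` times the exact
#' chemical-master-equation variance, where
#' `psi(z) = (2/z) (R(z) - 1) / (R(z) + 1)` and `z = -tau (k1 + k2)`.
#' At `z = 0` the removable singularity is filled by its limit
#' `psi(0) = 1` (any consistent method has `R(z) = 1 + z + O(z^2)`).
#'
#' @param R_eval a [butcher_tableau()], [stability_polynomial()], or a
#'   function evaluating `R(z)`.
#' @param z real value(s) `<= 0`.
#' @return `psi(z)`.  An error is raised at a variance pole `R(z) = -1`.
#' @examples
#' relative_variance(tableau_preset("poisson"), -1)    # 2
#' relative_variance(tableau_preset("poisson"), -1.5)  # 4
#' @export
relative_variance <- function(R_eval, z) {
  Rf <- as_R_evaluator(R_eval)
  if (length(z) > 1)
    return(vapply(z, function(zi) relative_variance(Rf, zi), numeric(1)))
  if (z > 0) stop("psi(z) is defined for z <= 0")
  if (z == 0) return(1)
  R <- Rf(z)
  if (abs(R + 1) < 1e-14)
    stop("variance pole: R(z) = -1 at z = ", format(z),
         " (requires R^2(z) != 1)")
  (2 / z) * (R - 1) / (R + 1)
}

# Largest l such that ok(z) holds on (-l, 0]: dense pre-scan plus bisection.
# Returns Inf (the horizon sentinel) if no violation is found on
# (-horizon, 0].  ok() must be vectorisable and TRUE near 0-.
interval_scan <- function(ok, horizon = 200, n_grid = 1e4, tol = 1e-6) {
  z <- seq(-horizon, 0, length.out = n_grid + 1L)[-(n_grid + 1L)]
  good <- ok(z)
  if (all(good)) return(Inf)
  if (!any(good)) return(0)
  # first violation when walking from 0- towards -horizon
  last_bad <- max(which(!good))
  lo <- z[last_bad]                       # violating
  hi <- if (last_bad < length(z)) z[last_bad + 1L] else 0  # satisfying
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  -(lo + hi) / 2
}

#' Stability interval on the negative real axis
#'
#' Returns the largest `l` such that `|R(z)| <= 1` for all `z` in
#' `(-l, 0]`, found by a dense pre-scan followed by bisection refinement.
#' If no violation is found down to `-horizon`, the horizon sentinel
#' `Inf` is returned (A-stable methods such as the implicit midpoint
#' rule).
#'
#' @inheritParams relative_variance
#' @param horizon scan limit `L_max` (default 200).
#' @param n_grid number of pre-scan points (default `1e4`); `psi` and
#'   `|R|` can violate constraints on thin windows between grid points for
#'   high stage counts, so the density is configurable.
#' @param tol absolute bisection tolerance on `l` (default `1e-6`).
#' @return Interval length `l >= 0`, or `Inf`.
#' @examples
#' stability_interval(tableau_preset("poisson"))  # 2
#' @export
stability_interval <- function(R_eval, horizon = 200, n_grid = 1e4,
                               tol = 1e-6) {
  Rf <- as_R_evaluator(R_eval)
  ok <- function(z) {
    R <- tryCatch(abs(Rf(z)), error = function(e) rep(Inf, length(z)))
    is.finite(R) & R <= 1
  }
  interval_scan(ok, horizon, n_grid, tol)
}

#' Variance-bounded interval
#'
#' Returns the largest `l` such that `|psi(z) - 1| < eps` for all `z` in
#' `(-l, 0]` — the design criterion for the variance-bounded tau-leap
#' methods.  Uses the same pre-scan plus bisection search as
#' [stability_interval()].
#'
#' @inheritParams stability_interval
#' @param eps variance tolerance in `(0, 1)`.
#' @examples
#' variance_bounded_interval(tableau_preset("poisson"), 0.5)  # 2/3
#' @export
variance_bounded_interval <- function(R_eval, eps, horizon = 200,
                                      n_grid = 1e4, tol = 1e-6) {
  stopifnot(eps > 0, eps < 1)
  Rf <- as_R_evaluator(R_eval)
  ok <- function(z) {
    ps <- vapply(z, function(zi) {
      tryCatch(relative_variance(Rf, zi), error = function(e) Inf)
    }, numeric(1))
    is.finite(ps) & abs(ps - 1) < eps
  }
  interval_scan(ok, horizon, n_grid, tol)
}

#' Matrix mean propagator R(tau W)
#'
#' For linear kinetics with matrix `W`, the ensemble mean of every
#' tau-leap method in this framework evolves as
#' `E[X_{n+1}] = R(tau W) E[X_n]`, where `R` is the matrix version of the
#' stability function:
#' `R(tau W) = I_N + (tau b' (x) W) (I_sN - tau A (x) W)^{-1} (e (x) I_N)`
#' (`(x)` the Kronecker product).  For diagonalizable `W` the eigenvalues
#' of the result are `R(tau lambda_i)`.
#'
#' @param tab a [butcher_tableau()].
#' @param tau step size `> 0` (`tau = 0` returns the identity).
#' @param W `N x N` kinetics matrix.
#' @return The `N x N` matrix `R(tau W)`.
#' @examples
#' W <- linear_kinetics_matrix(isomerisation_network(10, 10))$W
#' eigen(mean_propagator(tableau_preset("poisson"), 0.05, W))$values
#' @export
mean_propagator <- function(tab, tau, W) {
  stopifnot(inherits(tab, "butcher_tableau"), tau >= 0)
  W <- as.matrix(W)
  N <- nrow(W)
  stopifnot(ncol(W) == N)
  s <- tab$s
  e <- rep(1, s)
  K <- diag(s * N) - tau * kronecker(tab$A, W)
  right <- tryCatch(solve(K, kronecker(e, diag(N))),
                    error = function(err)
                      stop("singular Kronecker system in mean propagator"))
  unname(diag(N) + tau * kronecker(matrix(tab$b, 1), W) %*% right)
}

#' Read and write tableau files
#'
#' Serializes a [butcher_tableau()] (fields `s`, `A`, `b`, `w`) or a
#' [stability_polynomial()] (field `r`) as YAML.
#'
#' @param tab a [butcher_tableau()].
#' @param poly a [stability_polynomial()].
#' @param path file path.
#' @export
write_tableau <- function(tab, path) {
  stopifnot(inherits(tab, "butcher_tableau"))
  yaml::write_yaml(list(s = tab$s, A = apply(tab$A, 1, as.list),
                        b = as.numeric(tab$b), w = as.numeric(tab$w)),
                   path, precision = 17L)
  invisible(path)
}

#' @rdname write_tableau
#' @export
read_tableau <- function(path) {
  doc <- yaml::read_yaml(path)
  A <- do.call(rbind, lapply(doc$A, unlist))
  butcher_tableau(A, b = as.numeric(unlist(doc$b)),
                  w = as.numeric(unlist(doc$w)))
}

#' @rdname write_tableau
#' @export
write_stability_polynomial <- function(poly, path) {
  stopifnot(inherits(poly, "stability_polynomial"))
  yaml::write_yaml(list(r = as.numeric(poly$r)), path, precision = 17L)
  invisible(path)
}

#' @rdname write_tableau
#' @export
read_stability_polynomial <- function(path) {
  stability_polynomial(as.numeric(unlist(yaml::read_yaml(path)$r)))
}
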