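#' Closed-form two-stage method with bounded variance
#'
#' For the family of explicit two-stage tau-leap methods with stability
#' function `R(z) = 1 + z + gamma z^2` (`gamma = beta_2 alpha_21`), the
#' value of `gamma` that maximises the interval `(-l, 0]` on which the
#' stationary relative variance satisfies `|psi(z) - 1| < eps` has the
#' closed form
#' `gamma = (1 + eps) * ((1/2 + eps) - sqrt(eps (1 + eps)))`,
#' always in the bounded-variance regime `gamma > 1/8`.  The achieved
#' interval length is
#' `l = -(1/(1-eps) - 1/(2 gamma) - sqrt((1/(2 gamma) + 1/(1-eps))^2 - 2/gamma))`.
#'
#' @param eps variance tolerance in `(0, 1)`.
#' @param gamma two-stage coefficient; defaults to [two_stage_gamma()].
#' @return `two_stage_gamma()` returns `gamma`; `two_stage_interval()`
#'   returns the interval length `l`.
#' @examples
#' two_stage_gamma(0.5)                 # 0.20096...
#' two_stage_interval(0.5)              # 3.68026...
#' @export
two_stage_gamma <- function(eps) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 1)
    stop("eps must be a single value in (0, 1)")
  (1 + eps) * ((0.5 + eps) - sqrt(eps * (1 + eps)))
}

#' @rdname two_stage_gamma
#' @export
two_stage_interval <- function(eps, gamma = two_stage_gamma(eps)) {
  if (!is.numeric(eps) || length(eps) != 1 || eps <= 0 || eps >= 1)
    stop("eps must be a single value in (0, 1)")
  stopifnot(gamma > 0)
  rad <- (1 / (2 * gamma) + 1 / (1 - eps))^2 - 2 / gamma
  if (rad < 0)
    stop("no real interval endpoint (negative radicand) for eps = ",
         eps, ", gamma = ", gamma)
  # crossing of the lower band psi = 1 - eps (psi eventually decays)
  l <- -(1 / (1 - eps) - 1 / (2 * gamma) - sqrt(rad))
  # For gamma below the optimum (notably gamma <= 1/8, where psi grows
  # monotonically) the interior maximum of psi pierces the upper band
  # 1 + eps first: psi(z) = 1 + eps is the quadratic
  # (1+eps) gamma/2 z^2 + ((1+eps)/2 - gamma) z + eps = 0.
  # At the optimal gamma the maximum is tangent to the band
  # (discriminant 0); near-tangent discriminants are treated as that
  # tangency rather than as a genuine crossing.
  cc <- 1 + eps
  A <- cc * gamma / 2; B <- cc / 2 - gamma
  disc <- B^2 - 4 * A * eps
  if (disc > 1e-4) {
    z_up <- (-B + sqrt(disc)) / (2 * A)   # negative root closest to 0
    if (z_up < 0) l <- min(l, -z_up)
  }
  l
}

# The variance bound |psi(z)-1| < eps is equivalent to the sandwich
#   (1 + c z/2)/(1 - c z/2) < R(z) < (1 + c'z/2)/(1 - c'z/2)
# with c = 1+eps (lower) and c' = 1-eps (upper), both well defined for
# z < 0.  Both bounds lie in (-1, 1), so the sandwich implies |R| < 1.
psi_band <- function(z, cc) (1 + z * cc / 2) / (1 - z * cc / 2)

# Feasibility of the sandwich at fixed l, exactly, as a linear program.
# R(z) = 1 + z + sum_{j>=2} r_j z^j is linear in (r_2..r_s), so
# "minimise the maximum constraint violation t over a Chebyshev grid"
# is an LP in (r, t); min t < 0 certifies strict grid feasibility.
# Coefficients are solved in the scaled basis q_j = r_j l^j (u = z/l in
# (-1, 0)) to keep the constraint matrix well conditioned.
sandwich_lp <- function(l, s, eps, n_grid = 2000) {
  k <- seq_len(n_grid)
  u <- -0.5 * (1 - cos(pi * (2 * k - 1) / (2 * n_grid)))  # Chebyshev, (-1,0)
  z <- l * u
  lo <- psi_band(z, 1 + eps)
  up <- psi_band(z, 1 - eps)
  base <- 1 + z
  p <- s - 1L
  U <- outer(u, 2:s, `^`)
  obj <- c(rep(0, 2 * p), 1, -1)
  # Constraint (column) generation: solve the minimax LP on a subgrid,
  # then append the full-grid points its solution violates most, until
  # the subgrid optimum is optimal on the full grid.  At most ~2s
  # constraints are active at the optimum, so this converges in a few
  # small simplex solves instead of one 2*n_grid-row solve.
  S <- unique(c(seq(1L, n_grid, length.out = 200L), n_grid))
  solved <- -1
  for (round in 1:30) {
    US <- U[S, , drop = FALSE]
    # vars: q+ (p), q- (p), t+, t-;  minimise t = t+ - t-
    A1 <- rbind(cbind(US, -US, -1, 1), cbind(-US, US, -1, 1))
    b1 <- c(up[S] - base[S], base[S] - lo[S])
    sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, maxi = FALSE)
    solved <- sol$solved
    q <- sol$soln[seq_len(p)] - sol$soln[p + seq_len(p)]
    tS <- sol$soln[2 * p + 1] - sol$soln[2 * p + 2]
    R <- base + as.vector(U %*% q)
    viol <- pmax(lo - R, R - up)
    t_full <- max(viol)
    if (t_full <= tS + 1e-10) break
    worst <- order(viol, decreasing = TRUE)
    S <- unique(c(S, setdiff(worst, S)[seq_len(40L)]))
  }
  list(r = q / l^(2:s), t = t_full, solved = solved)
}

# Maximum of |psi(z)-1| - eps over a dense grid on (-l*(1-shrink), 0)
# (negative value = certified feasible on that grid).
certify_violation <- function(r, l, eps, n = 1e4, shrink = 1e-6) {
  z <- seq(-l * (1 - shrink), 0, length.out = n + 1L)[-(n + 1L)]
  R <- 1 + z
  zp <- z
  for (j in seq_along(r)) { zp <- zp * z; R <- R + r[j] * zp }
  ps <- (2 / z) * (R - 1) / (R + 1)
  max(abs(ps - 1)) - eps
}

#' Optimal variance-bounded stability polynomials
#'
#' Derives the coefficients `r_2, ..., r_s` of an explicit s-stage
#' stability polynomial `R(z) = 1 + z + sum_{j>=2} r_j z^j` that maximise
#' the length `l` of the interval `(-l, 0]` on which the stationary
#' relative variance obeys `|psi(z) - 1| < eps`.  The bound on `psi` is
#' equivalent to a two-sided sandwich on `R(z)` that is *linear* in the
#' coefficients, so the search is an outer bisection on `l` with an exact
#' linear-programming feasibility solve (simplex) on a Chebyshev grid at
#' each trial `l` — deterministic, with a certified global inner optimum.
#' The result is certified a posteriori on a dense grid and `l` is backed
#' off (never widened) until the certificate passes.
#'
#' @param s number of stages, `>= 2`.
#' @param eps variance tolerance in `(0, 1)`.
#' @param n_grid Chebyshev grid size for the feasibility LP (default
#'   2000).
#' @param l_tol bisection tolerance on `l` (default `1e-5`).
#' @param feas_tol feasibility margin required of the LP minimax
#'   violation (default `1e-8`).
#' @return An object of class `"optimization_result"`: list with `s`,
#'   `eps`, `r` (a [stability_polynomial()] including `r_1 = 1`), `l`,
#'   `tableau` (efficient subdiagonal form, from
#'   [tableau_from_polynomial()]) and `diagnostics` (bisection iteration
#'   count, LP minimax margin, certified maximum deviation of `psi` from
#'   1).
#' @examples
#' \donttest{
#' res <- optimize_polynomial(3, 0.5)
#' res$l            # about 8.12
#' }
#' @export
optimize_polynomial <- function(s, eps, n_grid = 2000, l_tol = 1e-5,
                                feas_tol = 1e-8) {
  stopifnot(s >= 2, s == round(s))
  if (!is.numeric(eps) || eps <= 0 || eps >= 1)
    stop("infeasible eps: must be in (0, 1)")
  s <- as.integer(s)
  lo <- 2 * eps / (1 + eps)   # the Poisson tau-leap bound, always feasible
  hi <- 2 * s^2               # Chebyshev bound on any real stability interval
  r <- NULL
  iters <- 0L
  t_at_lo <- NA_real_
  while (hi - lo > l_tol) {
    mid <- (lo + hi) / 2
    f <- sandwich_lp(mid, s, eps, n_grid)
    iters <- iters + 1L
    if (!f$solved %in% c(0, 1))
      stop("feasibility LP did not converge at l = ", format(mid),
           " (simplex status ", f$solved, ")")
    if (f$t < -feas_tol) { lo <- mid; r <- f$r; t_at_lo <- f$t } else hi <- mid
  }
  if (is.null(r)) stop("optimizer failed: no feasible interval found")
  # a-posteriori certification with back-off: the grid LP can overshoot l
  # by O(grid spacing^2); shrink until the dense certificate passes.
  l <- lo
  for (k in 1:20) {
    viol <- certify_violation(r, l, eps, n = 1e4, shrink = 1e-6)
    if (viol < 0) break
    l <- l * (1 - 2e-4)
    r <- sandwich_lp(l, s, eps, n_grid)$r
  }
  if (viol >= 0)
    stop("optimizer failed to certify feasibility (residual ",
         format(viol), ")")
  poly <- stability_polynomial(c(1, r))
  structure(list(s = s, eps = eps, r = poly, l = l,
                 tableau = tableau_from_polynomial(poly),
                 diagnostics = list(bisection_iters = iters,
                                    lp_margin = t_at_lo,
                                    cert_residual = viol)),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> s = %d, eps = %g: l = %.5f\n",
              x$s, x$eps, x$l))
  cat("  r =", format(x$r$r, digits = 6), "\n")
  invisible(x)
}

#' Efficient tableau realizing a stability polynomial
#'
#' Constructs the canonical efficient Runge-Kutta tau-leap tableau with a
#' given stability polynomial: weights `b = (0, ..., 0, 1)` and stage
#' matrix `A` zero except on the first subdiagonal, with
#' `alpha_{s-j+1, s-j} = r_{j+1} / r_j` so that the nested (Horner)
#' products reproduce `r_j = b' A^{j-1} e` exactly.  Methods in this form
#' admit the fixed-point-iteration step that needs only `s - 1` drift
#' evaluations per leap.
#'
#' @param poly a [stability_polynomial()] with `r_1 = 1` and no zero
#'   interior coefficient.
#' @return A [butcher_tableau()].
#' @examples
#' tableau_from_polynomial(stability_polynomial(c(1, 0.20096)))
#' @export
tableau_from_polynomial <- function(poly) {
  stopifnot(inherits(poly, "stability_polynomial"))
  r <- poly$r
  if (abs(r[1] - 1) > 1e-12)
    stop("subdiagonal construction requires r_1 = 1")
  s <- length(r)
  A <- matrix(0, s, s)
  if (s > 1) {
    if (any(r[-s] == 0) || r[s] == 0)
      stop("polynomial not realizable in subdiagonal form ",
           "(zero coefficient before the leading one)")
    for (j in seq_len(s - 1)) {
      # alpha on row s-j+1 ... : alpha_{s-j+1, s-j} = r_{j+1}/r_j
      A[s - j + 1, s - j] <- r[j + 1] / r[j]
    }
  }
  b <- c(rep(0, s - 1), 1)
  butcher_tableau(A, b)
}

#' Read and write optimizer results
#'
#' Serializes an [optimize_polynomial()] result (stages, tolerance,
#' coefficients, interval length, tableau) as a YAML document; these
#' documents back the `"rk-tauleap-s{S}-eps{E}"` presets of
#' [tableau_preset()].
#'
#' @param res an `"optimization_result"`.
#' @param path file path.
#' @export
write_optimization_result <- function(res, path) {
  stopifnot(inherits(res, "optimization_result"))
  yaml::write_yaml(list(s = res$s, eps = res$eps, r = as.numeric(res$r$r),
                        l = res$l), path, precision = 17L)
  invisible(path)
}

#' @rdname write_optimization_result
#' @export
read_optimization_result <- function(path) {
  doc <- yaml::read_yaml(path)
  poly <- stability_polynomial(as.numeric(unlist(doc$r)))
  structure(list(s = as.integer(doc$s), eps = doc$eps, r = poly,
                 l = doc$l, tableau = tableau_from_polynomial(poly),
                 diagnostics = NULL),
            class = "optimization_result")
}
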