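#' Reversible isomerisation test system
#'
#' The two-species reversible isomerisation `S1 <-> S2` (forward rate
#' `k1`, backward rate `k2`) with fixed total molecule count
#' `T = X1 + X2`.  Both channels are linear, the kinetics matrix is
#' `W = [[-k1, k2], [k1, -k2]]` with eigenvalues `0` and `-(k1 + k2)`,
#' and the chemical master equation is solvable in closed form — making
#' this the canonical scalar test system for tau-leap stability and
#' stationary-variance analysis, with `z = -tau (k1 + k2)`.
#'
#' @param k1,k2 rate constants, `> 0` (`k2 = 0` is allowed for the
#'   moments/pmf helpers' degenerate limit but not for the network).
#' @param T total molecule count.
#' @param X0 initial split (defaults to `(T/2, T/2)`).
#' @return `isomerisation_network()` returns a [reaction_network()];
#'   `isomerisation_stationary_moments()` a list with `mean` (length-2
#'   vector `T/(k1+k2) * (k2, k1)`) and `variance` (the common scalar
#'   `T k1 k2 / (k1 + k2)^2`); `isomerisation_stationary_pmf()` the
#'   Binomial(`T`, `p = k2/(k1+k2)`) probability mass of `X1` on
#'   `0:T`.
#' @examples
#' isomerisation_stationary_moments(10, 10, T = 200)
#' @export
isomerisation_network <- function(k1, k2, T = 200, X0 = NULL) {
  stopifnot(k1 > 0, k2 > 0, T >= 1, T == round(T))
  if (is.null(X0)) {
    stopifnot(T %% 2 == 0)
    X0 <- c(T / 2, T / 2)
  }
  stopifnot(length(X0) == 2, sum(X0) == T)
  reaction_network(
    species = c("S1", "S2"),
    nu = list(c(-1, 1), c(1, -1)),
    propensities = list(linear_propensity(c(S1 = k1)),
                        linear_propensity(c(S2 = k2))),
    initial_state = X0)
}

#' @rdname isomerisation_network
#' @export
isomerisation_stationary_moments <- function(k1, k2, T = 200) {
  stopifnot(k1 >= 0, k2 >= 0, k1 + k2 > 0)
  list(mean = T / (k1 + k2) * c(k2, k1),
       variance = T * k1 * k2 / (k1 + k2)^2)
}

#' @rdname isomerisation_network
#' @export
isomerisation_stationary_pmf <- function(k1, k2, T = 200) {
  stopifnot(k1 >= 0, k2 >= 0, k1 + k2 > 0)
  p <- k2 / (k1 + k2)
  stats::setNames(stats::dbinom(0:T, size = T, prob = p), 0:T)
}

#' Schlogl autocatalytic reaction system
#'
#' The scalar Schlogl system, the classical stiff nonlinear benchmark
#' with a bimodal stationary distribution:
#' `A + 2X -> 3X` (rate `k1`, propensity `k1 x (x-1) A / 2`),
#' `3X -> A + 2X` (`k2`, `k2 x (x-1) (x-2) / 6`),
#' `X -> B` (`k3`, `k3 x`), and `B -> X` (`k4`, `k4 B`).
#' The non-autocatalytic species `A` and `B` are buffered (held
#' constant) and folded into the channel rates, reducing the system to a
#' single species `X`.  The buffered counts are required configuration:
#' they are not part of the rate-constant defaults.
#'
#' `schlogl_default_scenario()` returns `A = 1e5`, `B = 2e5`,
#' `X0 = 250` — a reconstructed parameterization (the one of Cao et al.
#' that this system is conventionally run with), chosen to produce the
#' bimodal stationary density; it is a synthetic default, not a printed
#' reference value.
#'
#' @param A,B buffered molecule counts, `> 0` (required).
#' @param k1,k2,k3,k4 rate constants (defaults `3e-7`, `1e-4`, `3.5`,
#'   `1e-3`).
#' @param X0 initial count of `X`.
#' @return A single-species [reaction_network()] with four channels and
#'   `nu = (+1, -1, -1, +1)`.
#' @examples
#' sc <- schlogl_default_scenario()
#' net <- schlogl_network(A = sc$A, B = sc$B)
#' propensities(net, 2)   # (0.03, 0, 7, 200) with the defaults
#' @export
schlogl_network <- function(A, B, k1 = 3e-7, k2 = 1e-4, k3 = 3.5,
                            k4 = 1e-3, X0 = 250) {
  if (missing(A) || missing(B) || is.null(A) || is.null(B))
    stop("buffered counts A and B must be given explicitly")
  stopifnot(A > 0, B > 0)
  reaction_network(
    species = "X",
    nu = list(1, -1, -1, 1),
    propensities = list(
      mass_action(k1 * A, c(X = 2L)),
      mass_action(k2, c(X = 3L)),
      mass_action(k3, c(X = 1L)),
      mass_action(k4 * B)),
    initial_state = X0)
}

#' @rdname schlogl_network
#' @export
schlogl_default_scenario <- function() {
  list(A = 1e5, B = 2e5, X0 = 250)
}

#' Seeded random linear network fixture
#'
#' Generates a conservative unimolecular network: each of the `m`
#' channels transfers one molecule from a uniformly drawn species `i` to
#' a different species `j` (`nu = e_j - e_i`, propensity `rate * x_i`),
#' with rates drawn uniformly on `(0.5, 1.5) * rate_scale`.  Every
#' update vector sums to zero and the kinetics matrix `W` has zero
#' column sums (total molecule count is conserved in mean).  Intended as
#' a reproducible fixture for linear-theory property tests.
#'
#' @param seed integer seed; the same seed yields the same network.
#' @param N number of species, `>= 2`.
#' @param m number of transfer channels, `>= 1`.
#' @param rate_scale rate magnitude (default 1).
#' @param n0 mean initial copy number per species (default 50).
#' @return A [reaction_network()] with linear propensities.
#' @export
random_linear_network <- function(seed, N = 3, m = 4, rate_scale = 1,
                                  n0 = 50) {
  stopifnot(N >= 2, m >= 1)
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = .GlobalEnv))
  set.seed(seed)
  species <- paste0("S", seq_len(N))
  nu <- vector("list", m)
  props <- vector("list", m)
  for (jj in seq_len(m)) {
    ij <- sample.int(N, 2)
    v <- numeric(N)
    v[ij[1]] <- -1; v[ij[2]] <- 1
    nu[[jj]] <- v
    co <- numeric(N)
    co[ij[1]] <- rate_scale * stats::runif(1, 0.5, 1.5)
    props[[jj]] <- linear_propensity(co)
  }
  x0 <- stats::rpois(N, n0)
  reaction_network(species, nu, props, x0)
}
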