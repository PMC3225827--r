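#' Simulation kernel state
#'
#' A minimal state container for the single-step kernels: the state
#' vector `x` (integer-valued for SSA and Poisson tau-leap; real-valued
#' between Runge-Kutta leaps) and the current time `t`.
#'
#' @param x numeric state vector.
#' @param t time (default 0).
#' @return Object of class `"kernel_state"`.
#' @export
kernel_state <- function(x, t = 0) {
  structure(list(x = as.numeric(x), t = t), class = "kernel_state")
}

#' @export
print.kernel_state <- function(x, ...) {
  cat("<kernel_state> t =", format(x$t), " x =",
      paste(format(x$x), collapse = " "))
  if (isTRUE(attr(x, "absorbed"))) cat("  [absorbed]")
  if (isTRUE(attr(x, "failed"))) cat("  [failed]")
  cat("\n")
  invisible(x)
}

#' One exact SSA step
#'
#' Draws the waiting time to the next reaction from an exponential
#' distribution with rate `a_0(x) = sum_j a_j(x)`, selects the firing
#' channel `k` with probability `a_k/a_0` by cumulative-sum inversion,
#' and applies `x <- x + nu_k`.  When all propensities vanish the state
#' is absorbing: the input state is returned with attribute
#' `absorbed = TRUE` and no error.
#'
#' @param net a [reaction_network()].
#' @param state a [kernel_state()] with integer `x`.
#' @return Updated [kernel_state()].
#' @export
ssa_step <- function(net, state) {
  stopifnot(inherits(state, "kernel_state"))
  a <- propensities(net, state$x)
  if (any(a < 0)) stop("negative propensity in SSA at t = ", state$t)
  a0 <- sum(a)
  if (a0 == 0) {
    attr(state, "absorbed") <- TRUE
    return(state)
  }
  dt <- stats::rexp(1, rate = a0)
  u <- stats::runif(1) * a0
  k <- 1L
  acc <- a[1L]
  while (acc < u && k < length(a)) { k <- k + 1L; acc <- acc + a[k] }
  kernel_state(state$x + net$nu[, k], state$t + dt)
}

#' One Poisson tau-leap step
#'
#' Fires every channel `K_j ~ Poisson(tau a_j(x))` times over the leap
#' and applies `x <- x + sum_j nu_j K_j`; the state stays integer.  A
#' negative Poisson mean (a negative propensity following an excursion)
#' marks the step as failed (attribute `failed = TRUE`) rather than
#' raising an error.
#'
#' @param net a [reaction_network()].
#' @param state a [kernel_state()].
#' @param tau leap size `> 0`.
#' @return Updated [kernel_state()].
#' @export
poisson_tau_leap_step <- function(net, state, tau) {
  stopifnot(inherits(state, "kernel_state"), tau > 0)
  a <- propensities(net, state$x)
  if (any(tau * a < 0)) {
    attr(state, "failed") <- TRUE
    return(state)
  }
  x <- state$x
  for (j in seq_len(net$m)) {
    K <- stats::rpois(1, tau * a[j])
    x <- x + net$nu[, j] * K
  }
  kernel_state(x, state$t + tau)
}

# Shared weighted accumulation sum_j w_j v_j with fixed j order and zero
# weights skipped; both RK kernels (R and C) use this exact operation
# order so that algebraically equivalent formulations agree bitwise.
weighted_vector_sum <- function(vectors, weights, N) {
  acc <- numeric(N)
  for (j in seq_along(weights))
    if (weights[j] != 0) acc <- acc + weights[j] * vectors[[j]]
  acc
}

#' One Runge-Kutta tau-leap step (general explicit tableau)
#'
#' The s-stage Runge-Kutta tau-leap step draws ONE set of Poisson counts
#' `K_j ~ Poisson(tau a_j(X_n))` at the step start — the same number of
#' Poisson samples per step as the plain Poisson tau-leap — and forms the
#' compensated fluctuation `d_n = sum_j nu_j K_j - tau f(X_n)`.  The
#' stages are
#' `Y_i = X_n + tau sum_{j<i} alpha_ij f(Y_j) + w_i d_n`
#' and the update is
#' `X_{n+1} = X_n + tau sum_j beta_j f(Y_j) + d_n`.
#' With the `"poisson"` preset (`s = 1`) the step reproduces
#' [poisson_tau_leap_step()] bitwise under a shared RNG stream.  States
#' are real-valued between steps.
#'
#' The returned state carries attribute `drift_evals`: the number of
#' drift evaluations beyond the one at `X_n` (which is shared with the
#' Poisson means), i.e. `s - 1`.
#'
#' @param net a [reaction_network()].
#' @param tableau an explicit [butcher_tableau()] with `sum(b) = 1`.
#' @param state a [kernel_state()].
#' @param tau leap size `> 0`.
#' @param counts optional integer vector overriding the Poisson draws
#'   `K_j` (for deterministic-limit checks); `NULL` draws them.
#' @return Updated [kernel_state()].
#' @export
rk_tau_leap_step <- function(net, tableau, state, tau, counts = NULL) {
  stopifnot(inherits(tableau, "butcher_tableau"),
            inherits(state, "kernel_state"), tau > 0)
  if (!tableau$explicit)
    stop("simulation kernels require an explicit tableau")
  if (abs(sum(tableau$b) - 1) > 1e-12)
    stop("tableau weights must satisfy sum(b) = 1")
  x <- state$x
  N <- net$N
  a <- propensities(net, x)
  if (any(tau * a < 0)) {
    attr(state, "failed") <- TRUE
    return(state)
  }
  K <- if (is.null(counts)) stats::rpois(net$m, tau * a) else counts
  SnuK <- numeric(N)
  for (j in seq_len(net$m)) SnuK <- SnuK + net$nu[, j] * K[j]
  g0 <- tau * drift_from_propensities(net$nu, a)
  d <- SnuK - g0
  s <- tableau$s
  g <- vector("list", s)
  for (i in seq_len(s)) {
    Y <- x + tableau$w[i] * d
    for (j in seq_len(i - 1L))
      if (tableau$A[i, j] != 0) Y <- Y + tableau$A[i, j] * g[[j]]
    g[[i]] <- if (i == 1L) g0 else
      tau * drift_from_propensities(net$nu, propensities(net, Y))
  }
  correction <- weighted_vector_sum(g, tableau$b, N) - g0
  out <- kernel_state(x + SnuK + correction, state$t + tau)
  attr(out, "drift_evals") <- s - 1L
  out
}

#' One efficient Runge-Kutta tau-leap step (subdiagonal form)
#'
#' For tableaus in efficient form (`b = (0, ..., 0, 1)`, `A` nonzero only
#' on the first subdiagonal) the step collapses to the fixed-point
#' iteration
#' `Y_1 = X_n;  Y_i = X_n + alpha_{i,i-1} (tau f(Y_{i-1}) + d_n)`,
#' `X_{n+1} = X_n + tau f(Y_s) + d_n`,
#' which needs only `s - 1` drift evaluations beyond the step start.  The
#' result is bitwise identical to [rk_tau_leap_step()] on the same
#' tableau and RNG stream.
#'
#' @inheritParams rk_tau_leap_step
#' @export
rk_tau_leap_step_efficient <- function(net, tableau, state, tau,
                                       counts = NULL) {
  stopifnot(inherits(tableau, "butcher_tableau"),
            inherits(state, "kernel_state"), tau > 0)
  if (!is_efficient_form(tableau))
    stop("tableau not in efficient subdiagonal form; ",
         "use rk_tau_leap_step() for general tableaus")
  x <- state$x
  N <- net$N
  a <- propensities(net, x)
  if (any(tau * a < 0)) {
    attr(state, "failed") <- TRUE
    return(state)
  }
  K <- if (is.null(counts)) stats::rpois(net$m, tau * a) else counts
  SnuK <- numeric(N)
  for (j in seq_len(net$m)) SnuK <- SnuK + net$nu[, j] * K[j]
  g0 <- tau * drift_from_propensities(net$nu, a)
  d <- SnuK - g0
  s <- tableau$s
  gprev <- g0                      # tau * f(Y_1), Y_1 = X_n
  for (i in seq_len(s)[-1L]) {
    alpha <- tableau$A[i, i - 1L]
    Y <- x + alpha * d
    Y <- Y + alpha * gprev
    gprev <- tau * drift_from_propensities(net$nu, propensities(net, Y))
  }
  correction <- weighted_vector_sum(list(gprev), 1, N) - g0
  out <- kernel_state(x + SnuK + correction, state$t + tau)
  attr(out, "drift_evals") <- s - 1L
  out
}

is_efficient_form <- function(tab) {
  if (!tab$explicit) return(FALSE)
  s <- tab$s
  if (!identical(as.numeric(tab$b), c(rep(0, s - 1), 1))) return(FALSE)
  A <- tab$A
  off <- A
  if (s > 1) off[cbind(2:s, 1:(s - 1))] <- 0
  all(off == 0)
}
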