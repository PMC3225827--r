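# Encode a declarative network for the compiled engines.  Returns NULL
# when a channel uses a function propensity (the pure-R kernels are used
# instead).
encode_network <- function(net) {
  kinds <- vapply(net$propensities, `[[`, "", "kind")
  if (any(kinds == "function")) return(NULL)
  N <- net$N; m <- net$m
  kind <- integer(m)
  coef <- matrix(0, N, m)
  rate <- numeric(m)
  mult <- matrix(0L, N, m)
  for (j in seq_len(m)) {
    p <- net$propensities[[j]]
    if (p$kind == "linear") {
      kind[j] <- 0L
      coef[, j] <- p$coef
    } else {
      kind[j] <- 1L
      rate[j] <- p$rate
      if (length(p$reactants))
        mult[match(names(p$reactants), net$species), j] <-
          as.integer(p$reactants)
    }
  }
  list(nu = net$nu, kind = kind, coef = coef, rate = rate, mult = mult)
}

#' Simulate an ensemble of trajectories
#'
#' Runs `n_replicates` independent trajectories of a network under one of
#' the simulation methods and records end states and failures.
#' Replicates use independent L'Ecuyer-CMRG substreams derived from the
#' master `seed` by stream jumps (`parallel::nextRNGStream`), so results
#' are reproducible and independent of replicate execution order.
#'
#' Tau-leap replicates are *failed* when a Poisson mean is negative at a
#' step start or when any state coordinate leaves
#' `[-divergence_bound, divergence_bound]` (or becomes non-finite);
#' failed replicates are counted and their end states set to `NA` rather
#' than raising an error.  SSA trajectories that reach an absorbing state
#' simply retain it until `t_final`.
#'
#' @param net a [reaction_network()].
#' @param method `"ssa"`, `"poisson"`, or `"rk"` (which requires
#'   `tableau`).
#' @param tau fixed leap size (ignored for `"ssa"`); the trajectory takes
#'   `round(t_final / tau)` whole steps.
#' @param t_final final time.
#' @param n_replicates number of replicates (`0` gives an empty
#'   ensemble).
#' @param seed master seed (integer).
#' @param tableau explicit [butcher_tableau()] for `method = "rk"`.
#' @param kernel for `"rk"`: `"auto"` picks the efficient fixed-point
#'   kernel when the tableau is in subdiagonal form; `"general"` and
#'   `"efficient"` force a kernel (the two are bitwise-equivalent on
#'   subdiagonal tableaus).
#' @param divergence_bound magnitude beyond which a replicate is declared
#'   failed (default `1e12`).
#' @return Object of class `"trajectory_ensemble"`: `method`, `tau`,
#'   `t_final`, `n_replicates`, `end_states` (`n x N` matrix, `NA` rows
#'   for failures), `failed` (logical), `n_failed`, `seed`, `species`.
#' @examples
#' net <- isomerisation_network(10, 10)
#' ens <- simulate_ensemble(net, "poisson", tau = 0.05, t_final = 1,
#'                          n_replicates = 100, seed = 1)
#' empirical_moments(ens)
#' @export
simulate_ensemble <- function(net, method = c("ssa", "poisson", "rk"),
                              tau = NULL, t_final, n_replicates, seed,
                              tableau = NULL,
                              kernel = c("auto", "general", "efficient"),
                              divergence_bound = 1e12) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  stopifnot(inherits(net, "reaction_network"), t_final > 0,
            n_replicates >= 0)
  if (method != "ssa") {
    stopifnot(is.numeric(tau), tau > 0)
    n_steps <- as.integer(round(t_final / tau))
    if (n_steps < 1L) stop("t_final shorter than one leap")
  }
  if (method == "rk") {
    if (is.null(tableau)) stop("method 'rk' requires a tableau")
    if (!tableau$explicit)
      stop("simulators reject implicit tableaus (analysis only)")
    if (abs(sum(tableau$b) - 1) > 1e-12)
      stop("tableau weights must satisfy sum(b) = 1")
    if (kernel == "auto")
      kernel <- if (is_efficient_form(tableau)) "efficient" else "general"
    if (kernel == "efficient" && !is_efficient_form(tableau))
      stop("tableau not in efficient subdiagonal form")
  }
  enc <- encode_network(net)
  label <- if (method == "rk")
    paste0("rk(s=", tableau$s, ",", kernel, ")") else method

  end <- matrix(NA_real_, n_replicates, net$N,
                dimnames = list(NULL, net$species))
  failed <- logical(n_replicates)

  if (n_replicates > 0) {
    streams <- rng_substreams(seed, n_replicates)
    old <- get0(".Random.seed", envir = .GlobalEnv)
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = .GlobalEnv))
    for (i in seq_len(n_replicates)) {
      assign(".Random.seed", streams[[i]], envir = .GlobalEnv)
      res <- run_one(net, enc, method, kernel, tableau, tau,
                     if (method == "ssa") t_final else n_steps,
                     divergence_bound)
      failed[i] <- res$failed
      if (!res$failed) end[i, ] <- res$x
    }
  }
  structure(list(method = label, tau = tau, t_final = t_final,
                 n_replicates = n_replicates, end_states = end,
                 failed = failed, n_failed = sum(failed), seed = seed,
                 species = net$species),
            class = "trajectory_ensemble")
}

# Per-replicate L'Ecuyer-CMRG substreams of the master seed.
rng_substreams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = .GlobalEnv)
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  streams <- vector("list", n)
  if (n >= 1) {
    streams[[1]] <- get(".Random.seed", envir = .GlobalEnv)
    for (i in seq_len(n - 1L))
      streams[[i + 1L]] <- parallel::nextRNGStream(streams[[i]])
  }
  streams
}

run_one <- function(net, enc, method, kernel, tableau, tau, horizon,
                    div_bound) {
  x0 <- net$initial_state
  if (!is.null(enc)) {
    res <- switch(method,
      ssa = {
        out <- cpp_ssa(enc$nu, enc$kind, enc$coef, enc$rate, enc$mult,
                       x0, horizon, 1e9)
        list(x = out$x, failed = FALSE)
      },
      poisson = cpp_poisson_traj(enc$nu, enc$kind, enc$coef, enc$rate,
                                 enc$mult, x0, tau, horizon, div_bound),
      rk = if (kernel == "efficient") {
        alpha <- c(0, tableau$A[cbind(seq_len(tableau$s)[-1L],
                                      seq_len(tableau$s - 1L))])
        cpp_rk_eff_traj(enc$nu, enc$kind, enc$coef, enc$rate, enc$mult,
                        alpha, x0, tau, horizon, div_bound)
      } else {
        cpp_rk_traj(enc$nu, enc$kind, enc$coef, enc$rate, enc$mult,
                    tableau$A, tableau$b, tableau$w, x0, tau, horizon,
                    div_bound)
      })
    return(list(x = res$x, failed = isTRUE(res$failed)))
  }
  # pure-R fallback for networks with function propensities
  st <- kernel_state(x0)
  if (method == "ssa") {
    while (st$t < horizon) {
      nxt <- ssa_step(net, st)
      if (isTRUE(attr(nxt, "absorbed"))) break
      if (nxt$t > horizon) break
      st <- nxt
    }
    return(list(x = st$x, failed = FALSE))
  }
  stepper <- switch(method,
    poisson = function(s) poisson_tau_leap_step(net, s, tau),
    rk = if (kernel == "efficient")
      function(s) rk_tau_leap_step_efficient(net, tableau, s, tau)
    else function(s) rk_tau_leap_step(net, tableau, s, tau))
  for (k in seq_len(horizon)) {
    st <- stepper(st)
    if (isTRUE(attr(st, "failed"))) return(list(x = st$x, failed = TRUE))
    if (any(!is.finite(st$x)) || any(abs(st$x) > div_bound))
      return(list(x = st$x, failed = TRUE))
  }
  list(x = st$x, failed = FALSE)
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble>", x$method,
      if (!is.null(x$tau)) paste0("tau = ", x$tau), "t_final =", x$t_final,
      "\n  replicates:", x$n_replicates, " failed:", x$n_failed,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Record a single thinned trajectory
#'
#' Runs one replicate with the R step kernels, recording the state every
#' `thin` steps (every event for SSA).  Intended for plotting and the
#' command-line interface, not for large ensembles.
#'
#' @inheritParams simulate_ensemble
#' @param thin record every `thin`-th leap (tau-leap methods).
#' @return A data frame with columns `time` and one column per species.
#' @export
simulate_path <- function(net, method = c("ssa", "poisson", "rk"),
                          tau = NULL, t_final, seed, tableau = NULL,
                          thin = 1L) {
  method <- match.arg(method)
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = .GlobalEnv))
  set.seed(seed)
  st <- kernel_state(net$initial_state)
  rows <- list(c(time = st$t, stats::setNames(st$x, net$species)))
  k <- 0L
  repeat {
    if (method == "ssa") {
      nxt <- ssa_step(net, st)
      if (isTRUE(attr(nxt, "absorbed")) || nxt$t > t_final) break
      st <- nxt
    } else {
      if (st$t + tau > t_final + 1e-12) break
      st <- switch(method,
        poisson = poisson_tau_leap_step(net, st, tau),
        rk = rk_tau_leap_step(net, tableau, st, tau))
      if (isTRUE(attr(st, "failed"))) break
    }
    k <- k + 1L
    if (k %% thin == 0L)
      rows[[length(rows) + 1L]] <-
        c(time = st$t, stats::setNames(st$x, net$species))
  }
  as.data.frame(do.call(rbind, rows))
}
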