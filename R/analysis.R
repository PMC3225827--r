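ensemble_ok_states <- function(ens) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  ens$end_states[!ens$failed, , drop = FALSE]
}

#' Empirical ensemble moments
#'
#' Per-species sample mean and unbiased sample variance of the end
#' states over the successful replicates, with standard errors (the
#' variance SE uses the fourth-moment formula, valid beyond normality).
#'
#' @param ens a [simulate_ensemble()] result with at least two
#'   successful replicates.
#' @return List with `mean`, `var`, `se_mean`, `se_var` (named numeric
#'   vectors) and `n` (successful replicates).
#' @export
empirical_moments <- function(ens) {
  xs <- ensemble_ok_states(ens)
  n <- nrow(xs)
  if (n == 0) stop("all replicates failed")
  if (n < 2) stop("need at least 2 successful replicates")
  mu <- colMeans(xs)
  v <- apply(xs, 2, stats::var)
  m4 <- colMeans(sweep(xs, 2, mu)^4)
  se_var <- sqrt(pmax(m4 - (n - 3) / (n - 1) * v^2, 0) / n)
  list(mean = mu, var = v, se_mean = sqrt(v / n), se_var = se_var, n = n)
}

#' Relative stationary variance estimate
#'
#' Estimates `psi-hat = Var-hat[X_inf] / Var[X*]`: the ratio of the
#' empirical stationary end-state variance of one species to the exact
#' (analytic) stationary variance, with a bootstrap standard error.
#' Compared against the theoretical [relative_variance()] `psi(z)` this
#' is the empirical check that a method's stationary variance behaves as
#' its stability function predicts.
#'
#' @param ens a [simulate_ensemble()] result.
#' @param analytic_variance exact stationary variance, `> 0`.
#' @param species species index or name (default 1).
#' @param n_boot bootstrap replicates for the SE (default 200).
#' @return List with `psi_hat`, `se`, `n`.
#' @export
relative_variance_estimate <- function(ens, analytic_variance,
                                       species = 1L, n_boot = 200L) {
  stopifnot(analytic_variance > 0)
  xs <- ensemble_ok_states(ens)[, species]
  n <- length(xs)
  if (n < 2) stop("need at least 2 successful replicates")
  psi_hat <- stats::var(xs) / analytic_variance
  old <- get0(".Random.seed", envir = .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = .GlobalEnv))
  set.seed(10007L + n)    # internal, fixed: SEs are reproducible
  bo <- replicate(n_boot,
    stats::var(xs[sample.int(n, n, replace = TRUE)]) / analytic_variance)
  list(psi_hat = psi_hat, se = stats::sd(bo), n = n)
}

#' Kullback-Leibler divergence between pmfs (bits)
#'
#' `D(P_E, P_M) = sum_x P_E(x) log2(P_E(x) / P_M(x))` over the bins
#' where the reference pmf `P_E` is positive.  When the method pmf
#' `P_M` has empty bins on the support of `P_E` the divergence is
#' undefined; with `n_method` supplied, add-half (Jeffreys) pseudo-count
#' smoothing is applied to `P_M` only — identically across methods — and
#' the result carries attribute `smoothed = TRUE`.
#'
#' @param p_ref reference pmf `P_E` (sums to 1).
#' @param p_method method pmf `P_M`, on the same support, same length.
#' @param n_method sample count behind `p_method`, needed only when
#'   `p_method` has zeros on the support of `p_ref`.
#' @return Divergence in bits (`>= 0`, `0` iff identical on the support
#'   of `P_E`).
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))  # about 0.2075 bits
#' @export
kl_divergence <- function(p_ref, p_method, n_method = NULL) {
  stopifnot(length(p_ref) == length(p_method),
            all(p_ref >= 0), all(p_method >= 0))
  if (abs(sum(p_ref) - 1) > 1e-8) stop("p_ref must sum to 1")
  smoothed <- FALSE
  if (any(p_method == 0 & p_ref > 0)) {
    if (is.null(n_method))
      stop("p_method has empty bins on the support of p_ref; ",
           "supply n_method for add-half smoothing")
    K <- length(p_method)
    p_method <- (p_method * n_method + 0.5) / (n_method + 0.5 * K)
    smoothed <- TRUE
  }
  sup <- p_ref > 0
  d <- sum(p_ref[sup] * log2(p_ref[sup] / p_method[sup]))
  structure(d, smoothed = smoothed)
}

#' Empirical pmf of ensemble end states
#'
#' Bins one species' end states on an integer support (states from
#' Runge-Kutta methods are rounded to the nearest integer; SSA and
#' Poisson tau-leap states are already integer).  The support is the
#' union of `support` and all observed values — no truncation.
#'
#' @param ens a [simulate_ensemble()] result.
#' @param species species index or name.
#' @param support optional integer vector the pmf must cover (e.g. the
#'   support of an analytic reference).
#' @return Named numeric pmf over the integer support, with attribute
#'   `n` (sample count).
#' @export
empirical_pmf <- function(ens, species = 1L, support = NULL) {
  xs <- round(ensemble_ok_states(ens)[, species])
  if (!length(xs)) stop("all replicates failed")
  sup <- sort(unique(c(support, xs)))
  counts <- tabulate(match(xs, sup), nbins = length(sup))
  structure(stats::setNames(counts / length(xs), sup), n = length(xs))
}

#' Histogram comparison against a reference law
#'
#' Builds the shared-support comparison behind the Kullback-Leibler
#' reporting: the support is the union of observed integer values (after
#' rounding Runge-Kutta end states) of the method ensemble and, when the
#' reference is itself an ensemble, of the reference — no truncation.  An
#' analytic reference pmf is restricted to that support and renormalized.
#' [kl_divergence()] is then evaluated on the shared support, with
#' add-half smoothing of the method pmf only if it has empty bins there.
#'
#' @param ref reference law: a named analytic pmf (names are integer
#'   states, as from [isomerisation_stationary_pmf()]) or a
#'   [simulate_ensemble()] result (e.g. an SSA ensemble).
#' @param ens method ensemble to compare.
#' @param species species index or name (default 1).
#' @return List of class `"histogram_comparison"`: `support`, `p_ref`,
#'   `p_method`, `kl_bits`, `n_ref` (`NA` for an analytic reference),
#'   `n_method`, `smoothed`.
#' @export
histogram_comparison <- function(ref, ens, species = 1L) {
  p_m <- empirical_pmf(ens, species = species)
  if (inherits(ref, "trajectory_ensemble")) {
    p_r <- empirical_pmf(ref, species = species)
    n_ref <- attr(p_r, "n")
  } else {
    stopifnot(!is.null(names(ref)))
    p_r <- ref
    n_ref <- NA_integer_
  }
  support <- sort(unique(c(as.numeric(names(p_m)),
                           if (inherits(ref, "trajectory_ensemble"))
                             as.numeric(names(p_r)))))
  key <- as.character(support)
  pm <- stats::setNames(rep(0, length(support)), key)
  pm[names(p_m)] <- p_m
  pr <- stats::setNames(rep(0, length(support)), key)
  pr[intersect(names(p_r), key)] <- p_r[intersect(names(p_r), key)]
  pr <- pr / sum(pr)
  d <- kl_divergence(pr, pm, n_method = attr(p_m, "n"))
  structure(list(support = support, p_ref = pr, p_method = pm,
                 kl_bits = as.numeric(d), n_ref = n_ref,
                 n_method = attr(p_m, "n"),
                 smoothed = isTRUE(attr(d, "smoothed"))),
            class = "histogram_comparison")
}

#' @export
print.histogram_comparison <- function(x, ...) {
  cat("<histogram_comparison>", length(x$support), "bins,",
      "KL =", format(x$kl_bits, digits = 4), "bits",
      if (x$smoothed) "(method pmf smoothed)", "\n")
  invisible(x)
}

#' Ensemble failure rate
#'
#' Fraction of replicates aborted by the failure rules (negative Poisson
#' mean at a step start, non-finite or diverged state).  The attribute
#' `exceeds_1e3` flags rates above `1e-3`, the conventional reporting
#' threshold for declaring a method/step-size combination unreliable.
#'
#' @param ens a [simulate_ensemble()] result.
#' @return Failure rate in `[0, 1]` (0 for an empty ensemble).
#' @export
failure_rate <- function(ens) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  r <- if (ens$n_replicates == 0) 0 else ens$n_failed / ens$n_replicates
  structure(r, exceeds_1e3 = r > 1e-3)
}
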