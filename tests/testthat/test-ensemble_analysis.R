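make_ensemble <- function(states, failed = rep(FALSE, nrow(states))) {
  structure(list(method = "test", tau = 0.1, t_final = 1,
                 n_replicates = nrow(states),
                 end_states = states, failed = failed,
                 n_failed = sum(failed), seed = 0,
                 species = colnames(states)),
            class = "trajectory_ensemble")
}

test_that("empirical moments and failure accounting", {
  st <- matrix(c(2, 2, 2, 2, 2, 2), ncol = 1,
               dimnames = list(NULL, "A"))
  m <- empirical_moments(make_ensemble(st))
  expect_equal(unname(m$var), 0)    # degenerate ensemble
  expect_equal(unname(m$mean), 2)
  st2 <- matrix(rnorm(200, 50, 3), ncol = 2,
                dimnames = list(NULL, c("A", "B")))
  m2 <- empirical_moments(make_ensemble(st2))
  expect_equal(m2$mean, colMeans(st2))
  expect_equal(m2$var, apply(st2, 2, var))
  expect_equal(m2$n, 100)
  allfail <- make_ensemble(st2, failed = rep(TRUE, 100))
  allfail$end_states[] <- NA_real_
  expect_error(empirical_moments(allfail), "failed")
  expect_equal(as.numeric(failure_rate(allfail)), 1)
})

test_that("SSA ensemble variance and psi-hat agree with the exact CME", {
  net <- isomerisation_network(10, 10, T = 200)
  ens <- simulate_ensemble(net, "ssa", t_final = 0.5,
                           n_replicates = 4000, seed = 21)
  m <- empirical_moments(ens)
  expect_true(all(abs(m$var - 50) < 3 * m$se_var))
  rv <- relative_variance_estimate(ens, 50)
  expect_lt(abs(rv$psi_hat - 1), 3 * rv$se)
  expect_gt(rv$se, 0)
})

test_that("KL divergence: hand values, asymmetry, smoothing", {
  expect_equal(as.numeric(kl_divergence(c(0.5, 0.5), c(0.5, 0.5))), 0)
  d <- kl_divergence(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(as.numeric(d), 0.5 * log2(2) + 0.5 * log2(2 / 3),
               tolerance = 1e-12)
  expect_false(attr(d, "smoothed"))
  # asymmetric in its arguments
  d_rev <- kl_divergence(c(0.25, 0.75), c(0.5, 0.5))
  expect_false(isTRUE(all.equal(as.numeric(d), as.numeric(d_rev))))
  # zero method bins on the reference support need smoothing
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0)), "n_method")
  d_sm <- kl_divergence(c(0.5, 0.5), c(1, 0), n_method = 100)
  expect_true(attr(d_sm, "smoothed"))
  expect_gt(as.numeric(d_sm), 0)
  expect_error(kl_divergence(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("KL estimator stays under the exact-sampler calibration", {
  # drawing 1e4 exact binomial samples and comparing to the analytic pmf
  # on the observed support gives the finite-sample KL floor; it must
  # sit below the 0.005-bit acceptance threshold
  pmf <- isomerisation_stationary_pmf(10, 10, T = 200)
  set.seed(31)
  for (k in 1:3) {
    draws <- rbinom(1e4, 200, 0.5)
    ens <- make_ensemble(matrix(draws, ncol = 1,
                                dimnames = list(NULL, "S1")))
    hc <- histogram_comparison(pmf, ens)
    expect_lt(hc$kl_bits, 0.005)
    expect_equal(sum(hc$p_ref), 1)
    expect_equal(sum(hc$p_method), 1)
  }
})

test_that("empirical pmf rounds RK states and covers the union support", {
  st <- matrix(c(99.4, 100.6, 100.2, 101, 98.9), ncol = 1,
               dimnames = list(NULL, "S1"))
  p <- empirical_pmf(make_ensemble(st), support = 97:103)
  expect_equal(sum(p), 1)
  expect_equal(as.numeric(p[c("99", "100", "101")]), c(2, 1, 2) / 5)
  # observed values outside the given support extend it
  st2 <- matrix(c(97, 110), ncol = 1, dimnames = list(NULL, "S1"))
  p2 <- empirical_pmf(make_ensemble(st2), support = 97:103)
  expect_true("110" %in% names(p2))
})

test_that("psi-hat of preset methods brackets psi(z) on the isomerisation", {
  # small-scale restatement of the square-dot agreement between
  # simulated relative variances and the psi(z) curves
  net <- isomerisation_network(10, 10, T = 200)
  tab <- tableau_preset("rk-tauleap-s3-eps0.5")
  for (z in c(-1, -3)) {
    tau <- -z / 20
    ens <- simulate_ensemble(net, "rk", tau = tau, t_final = 200 * tau,
                             n_replicates = 2000, seed = 41,
                             tableau = tab)
    rv <- relative_variance_estimate(ens, 50)
    psi <- relative_variance(tab, z)
    expect_lt(abs(rv$psi_hat - psi), 3 * rv$se)
  }
})
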