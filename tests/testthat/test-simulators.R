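test_that("SSA step fires the only possible channel and detects absorption", {
  net <- iso_net(10, 10, T = 200, X0 = c(200, 0))
  set.seed(1)
  st <- ssa_step(net, kernel_state(c(200, 0)))
  expect_equal(st$x, c(199, 1))
  expect_gt(st$t, 0)
  dead <- reaction_network("A", list(-1), list(linear_propensity(1)), 0)
  st0 <- ssa_step(dead, kernel_state(0))
  expect_true(isTRUE(attr(st0, "absorbed")))
  expect_equal(st0$x, 0)
})

test_that("SSA extinction time matches the harmonic-sum oracle", {
  # pure decay from n0: E[T_ext] = sum_{i=1}^{n0} 1/(k i)
  k <- 1; n0 <- 5
  net <- decay_net(k, n0)
  n_rep <- 4000
  set.seed(1234)
  times <- replicate(n_rep, {
    st <- kernel_state(n0)
    repeat {
      st <- ssa_step(net, st)
      if (isTRUE(attr(st, "absorbed"))) break
    }
    st$t
  })
  oracle <- sum(1 / (k * seq_len(n0)))
  se <- stats::sd(times) / sqrt(n_rep)
  expect_lt(abs(mean(times) - oracle), 3.5 * se)
})

test_that("Poisson tau-leap step: zero propensities, one-step mean", {
  net0 <- reaction_network("A", list(1), list(mass_action(0)), 3)
  st <- poisson_tau_leap_step(net0, kernel_state(3), 0.1)
  expect_equal(st$x, 3)
  # one-step ensemble mean is x + tau f(x) within MC error
  net <- iso_net(10, 10, X0 = c(150, 50))
  tau <- 0.05
  ens <- simulate_ensemble(net, "poisson", tau = tau, t_final = tau,
                           n_replicates = 4000, seed = 5)
  m <- empirical_moments(ens)
  expected <- net$initial_state + tau * drift(net, net$initial_state)
  expect_true(all(abs(m$mean - expected) < 3.5 * m$se_mean))
})

test_that("RK kernel with the one-stage preset equals Poisson bitwise", {
  net <- iso_net(10, 10)
  po <- tableau_preset("poisson")
  # single step, shared RNG stream
  set.seed(77)
  a <- poisson_tau_leap_step(net, kernel_state(c(100, 100)), 0.05)
  set.seed(77)
  b <- rk_tau_leap_step(net, po, kernel_state(c(100, 100)), 0.05)
  expect_identical(a$x, b$x)
  # whole ensembles through the compiled engines
  e1 <- simulate_ensemble(net, "poisson", tau = 0.05, t_final = 2,
                          n_replicates = 300, seed = 9)
  e2 <- simulate_ensemble(net, "rk", tau = 0.05, t_final = 2,
                          n_replicates = 300, seed = 9, tableau = po,
                          kernel = "general")
  expect_identical(e1$end_states, e2$end_states)
})

test_that("efficient kernel is bitwise-equal to the general kernel", {
  sn <- schlogl_fixture()
  tab <- tableau_preset("rk-tauleap-s3-eps0.5")
  # 100 random single steps from random states, shared seeds
  set.seed(13)
  states <- sample(50:600, 100, replace = TRUE)
  for (i in seq_along(states)) {
    set.seed(1000 + i)
    a <- rk_tau_leap_step(sn, tab, kernel_state(states[i]), 0.4)
    set.seed(1000 + i)
    b <- rk_tau_leap_step_efficient(sn, tab, kernel_state(states[i]), 0.4)
    expect_identical(a$x, b$x)
  }
  # compiled engines over whole trajectories
  e1 <- simulate_ensemble(sn, "rk", tau = 0.4, t_final = 8,
                          n_replicates = 200, seed = 3, tableau = tab,
                          kernel = "general")
  e2 <- simulate_ensemble(sn, "rk", tau = 0.4, t_final = 8,
                          n_replicates = 200, seed = 3, tableau = tab,
                          kernel = "efficient")
  expect_identical(e1$end_states, e2$end_states)
  # the efficient step reports s - 1 drift evaluations
  set.seed(2)
  st <- rk_tau_leap_step_efficient(sn, tab, kernel_state(250), 0.4)
  expect_identical(attr(st, "drift_evals"), 2L)
  # Heun's tableau has b != (0, ..., 1): not in efficient form
  heun <- butcher_tableau(matrix(c(0, 1, 0, 0), 2, 2), b = c(0.5, 0.5))
  expect_error(
    rk_tau_leap_step_efficient(sn, heun, kernel_state(250), 0.4),
    "not in efficient subdiagonal form")
})

test_that("deterministic limit reproduces the classical RK step", {
  # replacing the Poisson draws by their means kills the fluctuation
  # term, leaving the underlying deterministic RK step on x' = f(x)
  sn <- schlogl_fixture()
  tab <- tableau_preset("rk-tauleap-s3-eps0.1")
  tau <- 0.4
  x0 <- 250
  a <- propensities(sn, x0)
  st <- rk_tau_leap_step(sn, tab, kernel_state(x0), tau, counts = tau * a)
  # classical RK oracle
  s <- tab$s
  Y <- numeric(s); g <- vector("list", s)
  for (i in seq_len(s)) {
    y <- x0
    for (j in seq_len(i - 1)) y <- y + tau * tab$A[i, j] * g[[j]]
    g[[i]] <- drift(sn, y)
  }
  x1 <- x0 + tau * sum(tab$b * unlist(g))
  expect_equal(st$x, x1, tolerance = 1e-10)
})

test_that("simulators reject implicit tableaus and bad weights", {
  net <- iso_net(10, 10)
  im <- tableau_preset("implicit-midpoint")
  expect_error(rk_tau_leap_step(net, im, kernel_state(c(100, 100)), 0.1),
               "explicit")
  expect_error(simulate_ensemble(net, "rk", tau = 0.1, t_final = 1,
                                 n_replicates = 2, seed = 1, tableau = im),
               "implicit")
  bad <- butcher_tableau(matrix(0, 1, 1), b = 0.7)
  expect_error(rk_tau_leap_step(net, bad, kernel_state(c(100, 100)), 0.1),
               "sum\\(b\\) = 1")
})

test_that("ensembles are reproducible and handle edge cases", {
  net <- iso_net(10, 10)
  e0 <- simulate_ensemble(net, "poisson", tau = 0.05, t_final = 1,
                          n_replicates = 0, seed = 1)
  expect_equal(nrow(e0$end_states), 0)
  expect_equal(e0$n_failed, 0)
  expect_equal(as.numeric(failure_rate(e0)), 0)
  e1 <- simulate_ensemble(net, "ssa", t_final = 0.2, n_replicates = 50,
                          seed = 42)
  e2 <- simulate_ensemble(net, "ssa", t_final = 0.2, n_replicates = 50,
                          seed = 42)
  expect_identical(e1$end_states, e2$end_states)
})

test_that("Poisson tau-leap is unstable beyond z = -2", {
  # k1 = k2 = 10 gives z = -20 tau; tau = 0.15 puts z = -3 well outside
  # the (-2, 0] stability interval and the ensemble variance diverges
  net <- iso_net(10, 10)
  ens <- simulate_ensemble(net, "poisson", tau = 0.15, t_final = 15,
                           n_replicates = 200, seed = 6)
  rate <- failure_rate(ens)
  expect_gt(as.numeric(rate), 0.9)
  expect_true(attr(rate, "exceeds_1e3"))
})

test_that("ensemble mean follows the matrix propagator on linear nets", {
  # E[X_n] = R(tau W)^n X_0 for every preset within its stability bound
  net <- iso_net(10, 10, X0 = c(150, 50))
  W <- unname(linear_kinetics_matrix(net)$W)
  tau <- 0.05; n_steps <- 5
  for (nm in c("poisson", "gillespie-midpoint", "rk-tauleap-s3-eps0.1")) {
    tab <- tableau_preset(nm)
    ens <- simulate_ensemble(net, "rk", tau = tau,
                             t_final = tau * n_steps,
                             n_replicates = 3000, seed = 17,
                             tableau = tab, kernel = "general")
    m <- empirical_moments(ens)
    P <- mean_propagator(tab, tau, W)
    theory <- P %*% P %*% P %*% P %*% P %*% net$initial_state
    expect_true(all(abs(m$mean - as.numeric(theory)) < 3.5 * m$se_mean),
                label = paste("mean propagation for", nm))
  }
})

test_that("single Poisson-set contract: m draws per step regardless of s", {
  # a function-propensity network counts its propensity evaluations; the
  # RK kernels must evaluate propensities once per stage but draw the
  # Poisson variates only once, so the RNG stream advances identically
  # for s = 1 and s = 3 (same number of draws)
  net <- iso_net(10, 10)
  tab3 <- tableau_preset("rk-tauleap-s3-eps0.1")
  set.seed(99)
  rk_tau_leap_step(net, tab3, kernel_state(c(100, 100)), 0.05)
  after3 <- .Random.seed
  set.seed(99)
  rk_tau_leap_step(net, tableau_preset("poisson"),
                   kernel_state(c(100, 100)), 0.05)
  after1 <- .Random.seed
  expect_identical(after3, after1)
})
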