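test_that("stability function matches known closed forms", {
  expect_equal(stability_function(tableau_preset("poisson"), -1), 0)
  expect_equal(stability_function(tableau_preset("implicit-midpoint"), -2),
               0)
  # 1 + z + z^2/2 at z = -2
  expect_equal(stability_function(tableau_preset("gillespie-midpoint"), -2),
               1)
  # implicit midpoint pole at z = 2
  expect_error(stability_function(tableau_preset("implicit-midpoint"), 2),
               "singular")
})

test_that("explicit stability functions equal their polynomial form", {
  set.seed(11)
  tabs <- list(tableau_preset("poisson"),
               tableau_preset("gillespie-midpoint"),
               two_stage_tableau(0.20096),
               tableau_preset("rk-tauleap-s3-eps0.1"),
               tableau_preset("rk-tauleap-s5-eps0.5"))
  for (tab in tabs) {
    poly <- stability_polynomial_from_tableau(tab)
    z <- -runif(50, 0, 5)
    Rpoly <- vapply(z, function(zi)
      1 + sum(poly$r * zi^seq_along(poly$r)), numeric(1))
    expect_equal(stability_function(tab, z), Rpoly, tolerance = 1e-12)
  }
  expect_error(
    stability_polynomial_from_tableau(tableau_preset("implicit-midpoint")),
    "rational")
})

test_that("stability polynomial coefficients r_j = b'A^(j-1)e", {
  expect_equal(
    stability_polynomial_from_tableau(tableau_preset("poisson"))$r, 1)
  expect_equal(
    stability_polynomial_from_tableau(tableau_preset("gillespie-midpoint"))$r,
    c(1, 0.5))
  expect_equal(stability_polynomial_from_tableau(two_stage_tableau(0.20096))$r,
               c(1, 0.20096))
})

test_that("relative variance psi has the documented closed forms", {
  po <- tableau_preset("poisson")
  expect_equal(relative_variance(po, -1), 2)     # variance doubles
  expect_equal(relative_variance(po, -1.5), 4)   # fourfold
  expect_error(relative_variance(po, -2), "pole")
  expect_equal(relative_variance(po, 0), 1)      # removable singularity
  # psi = 1/(1 + z/2) for the Poisson method on (-2, 0)
  set.seed(21)
  z <- -runif(50, 0, 2)
  expect_equal(relative_variance(po, z), 1 / (1 + z / 2),
               tolerance = 1e-12)
  # two-stage family: psi = (1 + g z)/(1 + z/2 + g z^2 / 2)
  for (g in c(0.20096, 0.3)) {
    tab <- two_stage_tableau(g)
    l <- variance_bounded_interval(tab, 0.5)
    z <- -runif(50, 0, l)
    expect_equal(relative_variance(tab, z),
                 (1 + g * z) / (1 + z / 2 + g * z^2 / 2),
                 tolerance = 1e-12)
  }
  # implicit midpoint preserves the variance for every z
  im <- tableau_preset("implicit-midpoint")
  expect_equal(relative_variance(im, c(-0.3, -5, -80)), rep(1, 3))
})

test_that("interval searches bracket their constraint boundary", {
  po <- tableau_preset("poisson")
  expect_equal(stability_interval(po), 2, tolerance = 1e-5)
  expect_gt(stability_interval(stability_polynomial(c(1, 0.20096))), 3.68)
  expect_identical(stability_interval(tableau_preset("implicit-midpoint")),
                   Inf)
  expect_equal(variance_bounded_interval(po, 0.5), 2 / 3,
               tolerance = 1e-5)
  expect_identical(
    variance_bounded_interval(tableau_preset("implicit-midpoint"), 0.25),
    Inf)
  g <- two_stage_gamma(0.5)
  l2 <- variance_bounded_interval(stability_polynomial(c(1, g)), 0.5)
  expect_equal(l2, 3.68026, tolerance = 1e-4)
  # monotone bisection contract: holds just inside, fails just outside
  delta <- 1e-5
  for (case in list(list(ev = po, eps = 0.5, l = 2 / 3),
                    list(ev = stability_polynomial(c(1, g)),
                         eps = 0.5, l = l2))) {
    psi_in <- relative_variance(case$ev, -(case$l - delta))
    psi_out <- relative_variance(case$ev, -(case$l + delta))
    expect_lt(abs(psi_in - 1), case$eps)
    expect_gte(abs(psi_out - 1), case$eps)
  }
})

test_that("mean propagator is the matrix stability function", {
  W <- unname(linear_kinetics_matrix(iso_net(10, 10))$W)
  po <- tableau_preset("poisson")
  tau <- 0.05
  expect_equal(mean_propagator(po, tau, W), diag(2) + tau * W)
  expect_equal(mean_propagator(po, 0, W), diag(2))
  # spectral mapping: eigenvalues are R(tau * lambda_i)
  set.seed(31)
  for (tab in list(tableau_preset("gillespie-midpoint"),
                   tableau_preset("implicit-midpoint"),
                   tableau_preset("rk-tauleap-s3-eps0.5"))) {
    for (N in c(2, 3)) {
      M <- matrix(rnorm(N * N), N)
      M <- M - diag(N) * max(abs(eigen(M)$values))  # push spectrum left
      ev_W <- eigen(M)$values
      P <- mean_propagator(tab, 0.1, M)
      mapped <- vapply(ev_W, function(lam)
        as.complex(stability_function(tab, as.complex(0.1 * lam))),
        complex(1))
      expect_equal(sort(Re(eigen(P)$values)), sort(Re(mapped)),
                   tolerance = 1e-8)
    }
  }
  # isomerisation: eigenvalues {1, R(-tau (k1 + k2))}
  P <- mean_propagator(po, tau, W)
  expect_equal(sort(eigen(P)$values),
               sort(c(1, stability_function(po, -tau * 20))),
               tolerance = 1e-10)
})

test_that("tableaus and polynomials round-trip through files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  tab <- tableau_preset("rk-tauleap-s3-eps0.25")
  write_tableau(tab, path)
  back <- read_tableau(path)
  expect_equal(back$A, tab$A)
  expect_equal(back$b, tab$b)
  expect_equal(back$w, tab$w)
  poly <- stability_polynomial(c(1, 0.25, 0.031))
  write_stability_polynomial(poly, path)
  expect_equal(read_stability_polynomial(path)$r, poly$r)
})

test_that("tableau invariants are enforced", {
  expect_error(butcher_tableau(matrix(c(0, 0.5, 0, 0), 2, 2), b = c(0, 1),
                               w = c(0.2, 0.3)), "A %*% e", fixed = TRUE)
  expect_false(tableau_preset("implicit-midpoint")$explicit)
  expect_true(tableau_preset("rk-tauleap-s5-eps0.1")$explicit)
  expect_equal(sum(tableau_preset("rk-tauleap-s5-eps0.1")$b), 1)
})
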