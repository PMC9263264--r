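test_that("jacobian anchors: decoupled and zero-state limits", {
  p <- decoupled_params(N_E = 5, N_I = 5, g = 0, sigma = 0)
  J <- sample_coupling(p, seed = 1)
  A <- network_jacobian(p, J, rep(0.7, 10))
  expect_equal(A, diag(-1, 10))
  # zero state with unit-slope odd transfer: -I + J
  p2 <- decoupled_params(N_E = 5, N_I = 5, g = 1, sigma = 0)
  J2 <- sample_coupling(p2, seed = 1)
  A2 <- network_jacobian(p2, J2, rep(0, 10))
  expect_equal(A2, as.matrix(J2) - diag(1, 10))
  expect_error(network_jacobian(p2, J2, rep(0, 7)), "length")
})

test_that("jacobian matches a finite-difference of the drift", {
  p <- small_fig3b(N_E = 30, N_I = 20, g = 1.5)
  J <- sample_coupling(p, seed = 2)
  Jm <- as.matrix(J)
  set.seed(3)
  x <- rnorm(50)
  v <- rnorm(50)
  drift <- function(x) -x + Jm %*% atan(x)
  h <- 1e-6
  fd <- as.vector(drift(x + h * v) - drift(x - h * v)) / (2 * h)
  expect_equal(as.vector(network_jacobian(p, J, x) %*% v), fd,
               tolerance = 1e-5)
})

test_that("spectral abscissa: identity shift property and anchors", {
  expect_equal(spectral_abscissa(diag(-1, 6)), -1)
  set.seed(4)
  for (i in 1:3) {
    A <- matrix(rnorm(64), 8, 8)
    expect_equal(spectral_abscissa(A - diag(1, 8)),
                 spectral_abscissa(A) - 1, tolerance = 1e-10)
  }
  expect_error(spectral_abscissa(matrix(1, 2, 3)), "square")
})

test_that("uncorrelated ensemble at unit derivative follows the circular law", {
  # random-matrix oracle: spectral radius of iid ensemble ~ g, so the
  # abscissa of -I + J at zero state is ~ g - 1
  p <- decoupled_params(N_E = 1200, N_I = 800, g = 0.6, sigma = 0)
  J <- sample_coupling(p, seed = 5)
  rho <- spectral_abscissa(network_jacobian(p, J, rep(0, p$N)))
  expect_lt(abs(rho - (p$g - 1)) / abs(p$g - 1), 0.05)
})

test_that("reciprocal correlation stretches the spectrum along the real axis", {
  rho_at <- function(eta) {
    p <- decoupled_params(N_E = 600, N_I = 400, g = 1, sigma = 0,
                          eta_E = eta, eta_I = eta)
    J <- sample_coupling(p, seed = 6)
    spectral_abscissa(network_jacobian(p, J, rep(0, p$N)))
  }
  expect_gt(rho_at(0.6), rho_at(0))
})

test_that("stability sweep recovers the decoupled anchor and a crossing", {
  # zero-mean network: at g = 0 the Jacobian is exactly -I
  p0 <- decoupled_params(N_E = 60, N_I = 40, sigma = 0.8)
  sw0 <- stability_sweep(p0, g_grid = c(0, 0.5), n_snapshots = 2,
                         burn_in = 10, seed = 1)
  expect_equal(tidy(sw0)$rho_mean[1], -1, tolerance = 1e-12)
  # anti-correlated E / correlated I preset: crossing between 1 and 1.6
  p <- small_fig3b()
  sw <- stability_sweep(p, g_grid = c(1.0, 1.3, 1.6), n_snapshots = 2,
                        burn_in = 20, seed = 1)
  summ <- tidy(sw)
  expect_lt(summ$rho_mean[summ$g == 1.0], 0)
  expect_gt(summ$rho_mean[summ$g == 1.6], 0)
  cross <- glance(sw)$crossing
  expect_true(cross > 1.0 && cross < 1.6)
})
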