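test_that("decoupled deterministic network decays exponentially", {
  p <- decoupled_params(sigma = 0, g = 0)
  J <- sample_coupling(p, seed = 1)
  x0 <- seq(-1, 1, length.out = p$N)
  tr <- integrate_network(p, J, x0 = x0, t_end = 3, dt = 0.001,
                          record_every = 1000)
  X <- rbind(tr$X_E, tr$X_I)
  for (i in seq_along(tr$times)) {
    expect_equal(X[, i], x0 * exp(-tr$times[i]), tolerance = 5e-3)
  }
})

test_that("integration is deterministic given (params, J, x0, seed)", {
  p <- decoupled_params(g = 1, sigma = 0.8)
  J <- sample_coupling(p, seed = 2)
  t1 <- integrate_network(p, J, t_end = 2, seed = 9)
  t2 <- integrate_network(p, J, t_end = 2, seed = 9)
  expect_identical(t1$X_E, t2$X_E)
  expect_identical(t1$X_I, t2$X_I)
  t3 <- integrate_network(p, J, t_end = 2, seed = 10)
  expect_false(identical(t1$X_E, t3$X_E))
})

test_that("divergent dynamics abort with the offending step", {
  p <- decoupled_params(N_E = 4, N_I = 4, sigma = 0)
  J <- sample_coupling(p, seed = 1)
  Jbad <- as.matrix(J)
  diag(Jbad) <- 500  # strong positive self-coupling blows the state up
  expect_error(
    eidyn:::em_run(Jbad, matrix(10, 8, 1), n_steps = 2000, dt = 0.05,
                   sigma = 0, phifun = function(x) x),
    "diverged at step")
})

test_that("replica pairs share noise and honour the offset contract", {
  p <- decoupled_params(g = 0, sigma = 0.8)
  J <- sample_coupling(p, seed = 1)
  # epsilon = 0: identical dynamics forever
  pr0 <- integrate_replica_pair(p, J, epsilon = 0, t_end = 2, seed = 4)
  d0 <- replica_distance(pr0)
  expect_true(all(d0$d_E == 0) && all(d0$d_I == 0))
  # decoupled: squared distance decays at exactly rate 2
  pr <- integrate_replica_pair(p, J, epsilon = 1e-4, t_end = 4, seed = 4)
  d <- replica_distance(pr)
  expect_equal(d$d_E[1], 1e-8, tolerance = 1e-12)
  expect_equal(d$d_E, 1e-8 * exp(-2 * d$time), tolerance = 2e-2)
  expect_equal(d$d_I, 1e-8 * exp(-2 * d$time), tolerance = 2e-2)
})

test_that("single-neuron-pair distance is plain arithmetic", {
  pair <- list(
    traj1 = list(times = c(0, 1), X_E = matrix(c(0, 0.3), 1),
                 X_I = matrix(c(0, 0), 1)),
    traj2 = list(times = c(0, 1), X_E = matrix(c(0, 0), 1),
                 X_I = matrix(c(0, 0), 1)),
    epsilon = 0)
  class(pair) <- "ei_replica_pair"
  d <- replica_distance(pair)
  expect_equal(d$d_E, c(0, 0.09))
})

test_that("replica distance matches its cross-covariance decomposition", {
  # d_K(t) ~ C11 + C22 - 2 C12 evaluated from the same pair of paths
  p <- small_fig3b(g = 3)
  J <- sample_coupling(p, seed = 6)
  pr <- integrate_replica_pair(p, J, epsilon = 0.05, t_end = 30, seed = 7)
  d <- replica_distance(pr)
  keep <- pr$traj1$times >= 20   # saturated regime
  x1 <- pr$traj1$X_E[, keep]
  x2 <- pr$traj2$X_E[, keep]
  m1 <- mean(x1); m2 <- mean(x2)
  c11 <- mean((x1 - m1)^2)
  c22 <- mean((x2 - m2)^2)
  c12 <- mean((x1 - m1) * (x2 - m2))
  d_pred <- c11 + c22 - 2 * c12
  d_obs <- mean(d$d_E[keep])
  expect_lt(abs(d_obs - d_pred) / d_obs, 0.15)
})

test_that("empirical autocorrelation: lag-0 is the windowed variance", {
  p <- decoupled_params(g = 0, sigma = 0.6)
  J <- sample_coupling(p, seed = 1)
  tr <- integrate_network(p, J, t_end = 60, dt = 0.02, seed = 3)
  ac <- empirical_autocorrelation(tr, burn_in = 20, tau_max = 3)
  keep <- tr$times >= 20
  XE <- tr$X_E[, keep]
  expect_equal(ac$C_E[1], mean((XE - mean(XE))^2), tolerance = 1e-12)
  # decoupled linear SDE: C(tau) = (sigma^2/2) exp(-tau)
  expect_equal(ac$C_E, (p$sigma^2 / 2) * exp(-ac$tau), tolerance = 0.25)
  expect_error(empirical_autocorrelation(tr, burn_in = 59, tau_max = 3),
               "t_end")
})

test_that("running autocorrelation estimate stabilizes after burn-in", {
  p <- small_fig2a()
  J <- sample_coupling(p, seed = 8)
  tr <- integrate_network(p, J, t_end = 100, dt = 0.02, seed = 9)
  diag0 <- stationarity_diagnostic(tr, tau = 0, window = 20)
  late <- diag0[diag0$t_start >= 50, ]
  expect_lt(stats::sd(late$C_E) / mean(late$C_E), 0.2)
})

test_that("halving dt leaves the stationary variance within sampling error", {
  p <- decoupled_params(N_E = 200, N_I = 100, g = 0, sigma = 0.8)
  J <- sample_coupling(p, seed = 1)
  est <- function(dt) {
    tr <- integrate_network(p, J, t_end = 60, dt = dt, seed = 5,
                            record_every = max(1L, round(0.1 / dt)))
    attr(empirical_autocorrelation(tr, burn_in = 20, tau_max = 1), "c_E0")
  }
  c_a <- est(0.02)
  c_b <- est(0.01)
  # sampling SE of the variance estimate is ~ c0 * sqrt(2 / n_eff)
  n_eff <- 300 * 40 / 2   # neurons x window / decorrelation time
  expect_lt(abs(c_a - c_b), 3 * c_a * sqrt(2 / n_eff) + 0.01)
})

test_that("exponents at zero gain equal the leak rate for both populations", {
  p <- decoupled_params(g = 0, sigma = 0.8)
  fit <- estimate_mle(p, seeds = 1, t_end = 30)
  expect_lt(abs(fit$lambda_E + 1), 0.05)
  expect_lt(abs(fit$lambda_I + 1), 0.05)
  # Benettin agrees in the decoupled limit
  fitb <- estimate_mle(p, seeds = 1, t_end = 20, method = "benettin")
  expect_lt(abs(fitb$lambda_E + 1), 0.05)
})

test_that("strong coupling produces a positive log-slope regime", {
  p <- small_fig3b(g = 3)
  fit <- estimate_mle(p, seeds = 1, t_end = 50)
  expect_gt(fit$lambda_E, 0)
  expect_gt(fit$lambda_I, 0)
})
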