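test_that("decoupled lag dynamics reproduce the exponential closed form", {
  p <- ei_preset("fig2a", g = 0)
  sol <- solve_self_consistency(p)
  cv <- integrate_autocorrelation(p, sol, tau_max = 2, dtau = 2e-4)
  expect_equal(cv$C_E, (p$sigma^2 / 2) * exp(-cv$tau), tolerance = 1e-7)
  expect_equal(cv$C_I, cv$C_E, tolerance = 1e-10)
  er <- energy_residual(cv, p, sol)
  expect_lt(max(er$res_E, er$res_I), 1e-8)
})

test_that("synchronized preset: equal curves, conserved energy, noise kick", {
  p <- ei_preset("fig2a")
  sol <- solve_self_consistency(p)
  cv <- integrate_autocorrelation(p, sol, tau_max = 5, dtau = 0.002)
  # condition (ii) preset: the two populations share one autocorrelation
  expect_lt(max(abs(cv$C_E - cv$C_I)), 1e-8)
  # curves stay in the admissible band
  expect_true(all(abs(cv$C_E) <= sol$c_E0 + 1e-8))
  # energy conservation along the lag dynamics
  er <- energy_residual(cv, p, sol)
  expect_lt(max(er$res_E, er$res_I), 1e-6)
  # the white noise contributes kinetic energy sigma^4/8 at lag 0+
  expect_equal(cv$dC_E[1]^2 / 2, p$sigma^4 / 8, tolerance = 1e-10)
  expect_equal(cv$dC_E[1], -p$sigma^2 / 2, tolerance = 1e-10)
})

test_that("lag-zero boundary values come from the self-consistent scalars", {
  p <- ei_preset("fig3b")
  sol <- solve_self_consistency(p)
  # outside the synchronization conditions the lag dynamics eventually
  # escape the admissible band (the saddle has no bounded orbit from these
  # boundary data): truncation returns the valid initial segment
  cv <- integrate_autocorrelation(p, sol, tau_max = 5,
                                  on_blowup = "truncate")
  expect_equal(cv$C_E[1], sol$c_E0)
  expect_equal(cv$C_I[1], sol$c_I0)
  expect_gt(nrow(cv), 100)
  # unbalanced correlations: the curves genuinely differ
  expect_gt(max(abs(cv$C_E / sol$c_E0 - cv$C_I / sol$c_I0)), 0.01)
  expect_error(integrate_autocorrelation(p, sol, tau_max = 5),
               "escaped")
})

test_that("gamma kernel matches its lag-0 substitution and is finite", {
  p <- ei_preset("fig2a")
  sol <- solve_self_consistency(p)
  cv <- integrate_autocorrelation(p, sol, tau_max = 2, dtau = 0.05)
  gk <- gamma_kernel(p, cv, sol)
  k <- eidyn:::kernel_coefs(p)
  expected0 <- p$g^2 * (k$a_E * eidyn:::f_phi(p$transfer, sol$c_E0,
                                              sol$c_E0) +
                          k$b_E * eidyn:::f_phi(p$transfer, sol$c_I0,
                                                sol$c_I0))
  expect_equal(gk$kappa_E[1], expected0, tolerance = 1e-10)
  expect_true(all(is.finite(gk$kappa_E)) && all(is.finite(gk$kappa_I)))
  expect_true(all(gk$kappa_E[1] >= gk$kappa_E - 1e-12))  # max at lag 0
})

test_that("gamma kernel matches the empirical recurrent-input covariance", {
  # network oracle: covariance of J_row . phi(x) from a direct simulation
  # (sub-critical gain, where the saddle-point reduction is quantitative)
  p <- small_fig2a(g = 1.0)
  sol <- solve_self_consistency(p)
  J <- sample_coupling(p, seed = 31)
  tr <- integrate_network(p, J, t_end = 60, dt = 0.02, seed = 32)
  keep <- tr$times >= 30
  X <- rbind(tr$X_E, tr$X_I)[, keep]
  inputs <- as.matrix(J)[seq_len(p$N_E), ] %*% atan(X)  # E-population drive
  centred <- inputs - rowMeans(inputs)
  kappa0_emp <- mean(centred^2)
  cv <- integrate_autocorrelation(p, sol, tau_max = 1, dtau = 0.5)
  gk <- gamma_kernel(p, cv, sol)
  expect_lt(abs(kappa0_emp - gk$kappa_E[1]) / gk$kappa_E[1], 0.2)
})
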