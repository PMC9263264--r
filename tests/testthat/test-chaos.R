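test_that("zero gain: the field contracts at twice the leak rate", {
  p <- ei_preset("fig2a", g = 0)
  sol <- solve_self_consistency(p)
  fld <- evolve_G(p, sol, t_max = 10)
  expect_equal(fld$rate_E, -2, tolerance = 1e-8)
  expect_equal(fld$rate_I, -2, tolerance = 1e-8)
  mle <- meanfield_mle(fld)
  expect_equal(unname(mle), c(-1, -1), tolerance = 1e-8)
})

test_that("balanced correlations with odd transfer equalize the field", {
  p <- ei_preset("fig2a")   # condition (ii)
  sol <- solve_self_consistency(p)
  fld <- evolve_G(p, sol, t_max = 15)
  expect_lt(max(abs(fld$log_diag_E - fld$log_diag_I)), 1e-8)
  expect_false(is.null(fld$G_E))
  expect_lt(max(abs(fld$G_E - fld$G_I)), 1e-8 * max(abs(fld$G_E)))
})

test_that("field growth rate changes sign across the critical condition", {
  # condition-(ii) setting without mean couplings, noisy
  p <- ei_params(N_E = 150, N_I = 100, m_EE = 0, m_EI = 0, m_IE = 0,
                 m_II = 0, g = 1, eta_E = 1 / 3, eta_I = 1 / 2,
                 sigma = 0.5)
  cr <- critical_g(p)
  expect_equal(cr$g_Ec, cr$g_Ic, tolerance = 1e-6)
  rate_at <- function(g) {
    pg <- eidyn:::set_gain(p, g)
    sol <- solve_self_consistency(pg)
    evolve_G(pg, sol, t_max = 25)$rate_E
  }
  expect_lt(rate_at(cr$g_Ec * 0.8), 0)
  expect_gt(rate_at(cr$g_Ec * 1.3), 0)
})

test_that("noise-free critical gain hits the analytic limits", {
  p <- decoupled_params(N_E = 100, N_I = 100, sigma = 0)
  cr <- critical_g(p)
  expect_equal(cr$g_Ec, 1, tolerance = 0.02)
  expect_equal(cr$g_Ic, 1, tolerance = 0.02)
  # single-population-like with pair correlation r: g_c = 1 / sqrt(1 + r)
  p2 <- decoupled_params(N_E = 100, N_I = 100, sigma = 0, eta_E = 0.5,
                         eta_I = 0.5)
  cr2 <- critical_g(p2)
  r <- 100 * 0.5 / 200
  expect_equal(cr2$g_Ec, 1 / sqrt(1 + r), tolerance = 0.02)
})

test_that("white noise raises the critical gain (chaos suppression)", {
  gI <- vapply(c(0, 0.4, 0.8), function(sig) {
    suppressWarnings(
      critical_g(ei_preset("fig3b", sigma = sig),
                 allow_partial = TRUE)$g_Ic)
  }, numeric(1))
  expect_true(all(diff(gI) > 0))
})

test_that("steeper transfer slope lowers the critical gain", {
  gc <- vapply(c(0.5, 1, 2), function(a) {
    p <- decoupled_params(N_E = 80, N_I = 80, sigma = 0,
                          transfer = transfer_spec("scaled_atan",
                                                   slope = a))
    critical_g(p, bracket = c(0.1, 5))$g_Ec
  }, numeric(1))
  expect_true(all(diff(gc) < 0))
})

test_that("stronger intra-population correlation promotes chaos", {
  # mean-field exponent nondecreasing in eta at fixed gain
  rates <- vapply(c(-0.5, 0, 0.5), function(eta) {
    p <- decoupled_params(N_E = 100, N_I = 100, g = 1.2, sigma = 0.5,
                          eta_E = eta, eta_I = eta)
    sol <- solve_self_consistency(p)
    evolve_G(p, sol, t_max = 20)$rate_E
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("the three critical-gain routes agree on a balanced preset", {
  p <- ei_params(N_E = 150, N_I = 100, m_EE = 0, m_EI = 0, m_IE = 0,
                 m_II = 0, g = 1, eta_E = 1 / 3, eta_I = 1 / 2,
                 sigma = 0.5)
  cr_cond <- critical_g(p)
  cr_field <- gfield_critical_g(p, g_grid = seq(0.8, 1.6, by = 0.2),
                                t_max = 25)
  expect_equal(cr_field$g_Ec, cr_field$g_Ic, tolerance = 1e-6)
  # condition vs field route: same transition within coarse-grid accuracy
  expect_lt(abs(cr_field$g_Ec - cr_cond$g_Ec), 0.25)
})
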