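test_that("stationary means: odd transfer and decoupled limits give zero", {
  expect_equal(as.numeric(stationary_means(ei_preset("fig2a"), 1, 1)),
               c(0, 0))
  p0 <- decoupled_params(transfer = transfer_spec("relu_atan"))
  expect_equal(as.numeric(stationary_means(p0, 0.5, 0.5)), c(0, 0),
               tolerance = 1e-10)
})

test_that("stationary means for the rectified preset satisfy back-substitution", {
  p <- ei_preset("fig2c")   # relu_atan, m_IE = 75, m_II = -50
  mu <- stationary_means(p, c_E0 = 0.5, c_I0 = 0.5)
  # independent substitution of the fixed-point equations
  # independent route: integrate() adaptive quadrature of the Gaussian mean
  gmean <- function(m) stats::integrate(
    function(x) pmax(atan(x), 0) * dnorm(x, m, sqrt(0.5)),
    -Inf, Inf, rel.tol = 1e-12)$value
  phiE <- gmean(mu[1])
  phiI <- gmean(mu[2])
  expect_lt(abs(mu[1] - p$m_EE * phiE - p$m_EI * phiI), 1e-8)
  expect_lt(abs(mu[2] - p$m_IE * phiE - p$m_II * phiI), 1e-8)
})

test_that("potentials and powers reduce to their closed forms at g = 0", {
  p <- ei_preset("fig2a", g = 0)
  V <- potentials(p, 0.4, 0.2, 1, 1)
  expect_equal(unname(V), c(-0.08, -0.02))
  W <- powers(p, 0.4, 0.2, 1, 1)
  expect_equal(unname(W), c(0.4, 0.2))
  # odd transfer, zero lag correlations: powers vanish
  W0 <- powers(ei_preset("fig2a"), 0, 0, 1, 1)
  expect_equal(unname(W0), c(0, 0), tolerance = 1e-12)
})

test_that("powers are minus the total C-directional derivative of potentials", {
  p <- ei_preset("fig2a")
  h <- 1e-5
  pt <- c(0.3, 0.25)
  c0 <- c(0.9, 0.8)
  Vp <- potentials(p, pt[1] + h, pt[2] + h, c0[1], c0[2])
  Vm <- potentials(p, pt[1] - h, pt[2] - h, c0[1], c0[2])
  W <- powers(p, pt[1], pt[2], c0[1], c0[2])
  expect_equal(unname(-(Vp - Vm) / (2 * h)), unname(W), tolerance = 1e-5)
  # partial in C_E alone recovers the single-population structure
  VpE <- potentials(p, pt[1] + h, pt[2], c0[1], c0[2])
  VmE <- potentials(p, pt[1] - h, pt[2], c0[1], c0[2])
  k <- eidyn:::kernel_coefs(p)
  expected <- -pt[1] + p$g^2 * k$a_E *
    eidyn:::f_phi(p$transfer, pt[1], c0[1])
  expect_equal(unname((VpE[1] - VmE[1]) / (2 * h)), expected,
               tolerance = 1e-5)
})

test_that("self-consistency: odd transfer kills the long-lag limits", {
  for (preset in c("fig2a", "fig3b")) {
    sol <- solve_self_consistency(ei_preset(preset))
    expect_true(sol$converged)
    expect_lt(abs(sol$c_Einf), 1e-8)
    expect_lt(abs(sol$c_Iinf), 1e-8)
    expect_gte(sol$c_E0, sol$c_Einf)
    expect_gte(sol$c_I0, sol$c_Iinf)
    expect_lt(max(abs(sol$residuals)), 1e-8)
  }
})

test_that("noise-free subcritical solve sits on the zero branch", {
  sol <- solve_self_consistency(ei_preset("fig2a", sigma = 0, g = 0.5))
  expect_identical(sol$branch, "zero")
  expect_identical(sol$c_E0, 0)
  expect_identical(sol$c_I0, 0)
  # supercritical: nonzero (chaotic) root returned, zero root recorded
  sol2 <- solve_self_consistency(ei_preset("fig2a", sigma = 0, g = 1.5))
  expect_identical(sol2$branch, "chaotic")
  expect_gt(sol2$c_E0, 0.1)
  expect_gt(length(sol2$alt_roots), 0)
})

test_that("decoupled noisy network recovers c0 = sigma^2 / 2 exactly", {
  p <- ei_preset("fig2a", g = 0)
  sol <- solve_self_consistency(p)
  expect_equal(sol$c_E0, p$sigma^2 / 2, tolerance = 1e-9)
  expect_equal(sol$c_I0, p$sigma^2 / 2, tolerance = 1e-9)
  expect_equal(sol$c_Einf, 0, tolerance = 1e-10)
})

test_that("mean-field variance matches network simulations sub-critically", {
  # quantitative agreement holds away from the chaos transition; at the
  # baseline gain g = 1.4 (essentially at the noisy transition) finite-size
  # fluctuations inflate the simulated variance, see the methods vignette
  for (case in list(list(g = 0.6, tol = 0.05), list(g = 1.0, tol = 0.12))) {
    p <- small_fig2a(g = case$g)
    sol <- solve_self_consistency(p)
    J <- sample_coupling(p, seed = 21)
    tr <- integrate_network(p, J, t_end = 150, dt = 0.02, seed = 22)
    ac <- empirical_autocorrelation(tr, burn_in = 50, tau_max = 2)
    expect_lt(abs(attr(ac, "c_E0") - sol$c_E0) / sol$c_E0, case$tol)
    expect_lt(abs(attr(ac, "c_I0") - sol$c_I0) / sol$c_I0, case$tol)
  }
})

test_that("synchronization conditions classify the presets", {
  cA <- check_synchronization_conditions(ei_preset("fig2a"))
  expect_true(cA[["cond_ii"]])
  expect_true(attr(cA, "any"))
  cB <- check_synchronization_conditions(ei_preset("fig2b"))
  expect_false(any(cB))
  cI <- check_synchronization_conditions(decoupled_params())
  expect_true(cI[["cond_i"]])
  # condition (iii): equal means supplied directly, balanced correlations
  cIII <- check_synchronization_conditions(ei_preset("fig2a"),
                                           means = c(0.2, 0.2))
  expect_true(cIII[["cond_iii"]])
})
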