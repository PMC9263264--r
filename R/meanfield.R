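#' @title Gaussian pair expectations (bivariate quadrature)
#' @description
#' Computes `E[f(z1 + mu) f(z2 + mu)]` where `(z1, z2)` is bivariate normal
#' with zero means, common variance `c0`, and covariance `C`. This is the
#' basic building block of the mean-field reduction: with `f` the transfer
#' function it gives the rate autocorrelation `<phi(x(t)) phi(x(t + tau))>`
#' as a function of the state autocorrelation `C` and variance `c0`.
#'
#' The integral is evaluated by conditioning, `z2 = (C/c0) z1 +
#' sqrt(c0 - C^2/c0) w` with `w` independent standard normal, followed by
#' tensor Gauss-Hermite quadrature (64 nodes per axis). The degenerate
#' limits are handled analytically: `c0 = 0` returns `f(mu)^2`, and
#' `|C| = c0` collapses to a single integral with `z2 = sign(C) z1`.
#'
#' @param fn Vectorized scalar function.
#' @param C Covariance, with `|C| <= c0`.
#' @param c0 Common variance, `>= 0`.
#' @param mu Mean offset applied inside `fn` (default 0).
#' @return A scalar expectation.
#' @examples
#' gaussian_pair_expectation(identity, C = 0.3, c0 = 1)  # returns C
#' @export
gaussian_pair_expectation <- function(fn, C, c0, mu = 0) {
  if (!is.finite(C) || !is.finite(c0)) stop("C and c0 must be finite")
  if (c0 < 0) stop("`c0` must be >= 0", call. = FALSE)
  if (abs(C) > c0 + 1e-10 * max(c0, 1))
    stop(sprintf("|C| = %g exceeds c0 = %g: not a valid covariance",
                 abs(C), c0), call. = FALSE)
  gh <- gh_nodes()
  if (c0 < 1e-14) return(fn(mu)^2)
  s1 <- sqrt(c0)
  z1 <- s1 * gh$z
  if (c0 - abs(C) < 1e-12 * max(c0, 1)) {
    if (C >= 0) return(sum(gh$w * fn(z1 + mu)^2))
    return(sum(gh$w * fn(z1 + mu) * fn(-z1 + mu)))
  }
  s2 <- sqrt(c0 - C^2 / c0)
  m2 <- (C / c0) * z1
  # inner expectation over w for each outer node, vectorized as outer sums
  Z2 <- outer(m2, s2 * gh$z, `+`)            # n x n matrix of z2 values
  inner <- as.vector(fn(Z2 + mu) %*% gh$w)
  sum(gh$w * fn(z1 + mu) * inner)
}

# cached 64-node Gauss-Hermite rule mapped to the standard normal measure
gh_env <- new.env(parent = emptyenv())
gh_nodes <- function(n = 64L) {
  key <- as.character(n)
  if (is.null(gh_env[[key]])) {
    r <- pracma::gaussHermite(n)
    gh_env[[key]] <- list(z = sqrt(2) * r$x, w = r$w / sqrt(pi))
  }
  gh_env[[key]]
}

# univariate E[fn(z + mu)], z ~ N(0, c0)
gaussian_mean <- function(fn, c0, mu = 0) {
  if (c0 < 0) stop("`c0` must be >= 0", call. = FALSE)
  if (c0 < 1e-14) return(fn(mu))
  gh <- gh_nodes()
  sum(gh$w * fn(sqrt(c0) * gh$z + mu))
}

# ---- truncated quadrature for the rectified (kinked) transfer -------------
#
# Gauss-Hermite converges slowly on integrands with a kink, so expectations
# involving max(arctan(.), 0) are computed as integrals of the smooth
# arctan branch over the truncated domain z > lo, with Gauss-Legendre nodes
# (spectrally accurate on each smooth piece).

gl_env <- new.env(parent = emptyenv())
gl_base <- function(n = 48L) {
  key <- as.character(n)
  if (is.null(gl_env[[key]])) gl_env[[key]] <- pracma::gaussLegendre(n, -1, 1)
  gl_env[[key]]
}

# int_{lo}^{hi} g(z) dnorm(z, m, s) dz by scaled Gauss-Legendre
trunc_norm_int <- function(g, m, s, lo, span = 8.5, n = 48L) {
  a <- max(lo, m - span * s)
  b <- m + span * s
  if (a >= b) return(0)
  base <- gl_base(n)
  z <- (a + b) / 2 + (b - a) / 2 * base$x
  w <- (b - a) / 2 * base$w
  sum(w * g(z) * stats::dnorm(z, m, s))
}

# E[g1(z1) 1(z1 > lo) g2(z2) 1(z2 > lo)] under the equicorrelated
# bivariate normal (variances c0, covariance C)
trunc_pair_expect <- function(g1, g2, C, c0, lo) {
  if (c0 < 1e-14) {
    return(if (0 > lo) g1(0) * g2(0) else 0)
  }
  s1 <- sqrt(c0)
  if (c0 - abs(C) < 1e-12 * max(c0, 1)) {
    if (C >= 0) {
      return(trunc_norm_int(function(z) g1(z) * g2(z), 0, s1, lo))
    }
    # z2 = -z1: both indicators give z1 in (lo, -lo)
    if (-lo <= lo) return(0)
    base <- gl_base()
    a <- max(lo, -8.5 * s1); b <- min(-lo, 8.5 * s1)
    if (a >= b) return(0)
    z <- (a + b) / 2 + (b - a) / 2 * base$x
    w <- (b - a) / 2 * base$w
    return(sum(w * g1(z) * g2(-z) * stats::dnorm(z, 0, s1)))
  }
  s2 <- sqrt(c0 - C^2 / c0)
  outer_fun <- function(z1vec) {
    vapply(z1vec, function(z1) {
      trunc_norm_int(g2, (C / c0) * z1, s2, lo)
    }, numeric(1))
  }
  trunc_norm_int(function(z) g1(z) * outer_fun(z), 0, s1, lo)
}

# smooth branches of the rectified transfer, as functions of z (state),
# kink at z = -mu
relu_branches <- function(mu) {
  list(lo = -mu,
       phi = function(z) atan(z + mu),
       dphi = function(z) 1 / (1 + (z + mu)^2),
       anti = function(z) {
         x <- z + mu
         x * atan(x) - log1p(x^2) / 2
       })
}

# f_phi, f_phi', f_rho for a transfer spec with population mean offset mu.
# rho(x) = Phi(x + mu) - Phi(mu) is the antiderivative of the shifted
# transfer, so by Price's theorem d f_rho / dC = f_phi. Smooth (odd)
# transfers use Gauss-Hermite; the rectified transfer uses the truncated
# Gauss-Legendre path above.
check_pair_domain <- function(C, c0) {
  if (c0 < 0) stop("`c0` must be >= 0", call. = FALSE)
  if (abs(C) > c0 + 1e-10 * max(c0, 1))
    stop(sprintf("|C| = %g exceeds c0 = %g: not a valid covariance",
                 abs(C), c0), call. = FALSE)
}

f_phi <- function(spec, C, c0, mu = 0) {
  if (spec$name == "relu_atan") {
    check_pair_domain(C, c0)
    br <- relu_branches(mu)
    return(trunc_pair_expect(br$phi, br$phi, C, c0, br$lo))
  }
  gaussian_pair_expectation(function(x) tf_value(spec, x), C, c0, mu)
}
f_phiprime <- function(spec, C, c0, mu = 0) {
  if (spec$name == "relu_atan") {
    check_pair_domain(C, c0)
    br <- relu_branches(mu)
    return(trunc_pair_expect(br$dphi, br$dphi, C, c0, br$lo))
  }
  gaussian_pair_expectation(function(x) tf_deriv(spec, x), C, c0, mu)
}
f_rho <- function(spec, C, c0, mu = 0) {
  if (spec$name == "relu_atan") {
    check_pair_domain(C, c0)
    br <- relu_branches(mu)
    K <- tf_anti(spec, mu)
    Euu <- trunc_pair_expect(br$anti, br$anti, C, c0, br$lo)
    Eu <- if (c0 < 1e-14) {
      if (0 > br$lo) br$anti(0) else 0
    } else trunc_norm_int(br$anti, 0, sqrt(c0), br$lo)
    return(Euu - 2 * K * Eu + K^2)
  }
  rho <- function(x) tf_anti(spec, x + mu) - tf_anti(spec, mu)
  gaussian_pair_expectation(rho, C, c0, mu = 0)
}

# E[phi(z + mu)], z ~ N(0, c0), accurate for all transfer families
phi_mean <- function(spec, c0, mu = 0) {
  if (spec$name == "relu_atan") {
    if (c0 < 1e-14) return(tf_value(spec, mu))
    br <- relu_branches(mu)
    return(trunc_norm_int(br$phi, 0, sqrt(c0), br$lo))
  }
  gaussian_mean(tf_fun(spec), c0, mu)
}

# population weight coefficients of the effective-noise kernel:
# row K of the 2x2 matrix multiplies (f_E, f_I);
# a_E = N_E (1 + eta_E) / N, b_E = N_I / N, etc.
kernel_coefs <- function(params) {
  with(params, list(
    a_E = N_E * (1 + eta_E) / N, b_E = N_I / N,
    a_I = N_E / N,               b_I = N_I * (1 + eta_I) / N))
}

#' Stationary population means
#'
#' Solves the fixed-point equations for the stationary means,
#' `<x_E> = m_EE <phi(x_E)> + m_EI <phi(x_I)>` (and the I row), where
#' `<phi(x_K)>` is the Gaussian mean of the transfer function at variance
#' `c_K0` around `<x_K>`. For an odd transfer function `(0, 0)` is the
#' consistent solution and is returned after verification.
#'
#' @param params An [ei_params()] object.
#' @param c_E0,c_I0 Variances entering the Gaussian averages.
#' @return Named vector `c(mean_E, mean_I)` with back-substitution residual
#'   below `1e-8` (attribute `residual`).
#' @export
stationary_means <- function(params, c_E0 = 0, c_I0 = 0) {
  spec <- params$transfer
  resid <- function(mu) {
    pE <- phi_mean(spec, c_E0, mu[1])
    pI <- phi_mean(spec, c_I0, mu[2])
    c(mu[1] - params$m_EE * pE - params$m_EI * pI,
      mu[2] - params$m_IE * pE - params$m_II * pI)
  }
  if (spec$is_odd) {
    mu <- c(0, 0)
  } else {
    # damped fixed-point warm start, then Newton
    mu <- c(0, 0)
    for (i in 1:40) {
      pE <- phi_mean(spec, c_E0, mu[1])
      pI <- phi_mean(spec, c_I0, mu[2])
      mu_new <- c(params$m_EE * pE + params$m_EI * pI,
                  params$m_IE * pE + params$m_II * pI)
      mu <- 0.5 * mu + 0.5 * mu_new
    }
    sol <- newton_system(resid, mu, tol = 1e-12)
    if (!sol$converged)
      stop("stationary-mean solve did not converge; last residual = ",
           format(max(abs(sol$fx))), call. = FALSE)
    mu <- sol$x
  }
  r <- resid(mu)
  if (max(abs(r)) > 1e-8)
    stop("stationary means failed back-substitution: residual = ",
         format(max(abs(r))), call. = FALSE)
  out <- c(mean_E = mu[1], mean_I = mu[2])
  attr(out, "residual") <- max(abs(r))
  out
}

# small damped Newton with numerical Jacobian and step-halving; used for the
# 2-d root problems of the self-consistency machinery
newton_system <- function(f, x0, tol = 1e-10, max_iter = 100,
                          lower = NULL, upper = NULL) {
  x <- x0
  clamp <- function(x) {
    if (!is.null(lower)) x <- pmax(x, lower)
    if (!is.null(upper)) x <- pmin(x, upper)
    x
  }
  x <- clamp(x)
  fx <- f(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(fx)) < tol)
      return(list(x = x, fx = fx, converged = TRUE, iterations = it - 1L))
    n <- length(x)
    Jac <- matrix(0, n, n)
    h <- pmax(1e-7, 1e-7 * abs(x))
    for (j in seq_len(n)) {
      xp <- x; xp[j] <- x[j] + h[j]
      xm <- x; xm[j] <- x[j] - h[j]
      xm <- clamp(xm); xp <- clamp(xp)
      denom <- xp[j] - xm[j]
      if (denom == 0) denom <- h[j]
      Jac[, j] <- (f(xp) - f(xm)) / denom
    }
    step <- tryCatch(solve(Jac, fx), error = function(e) fx)
    lam <- 1
    repeat {
      x_new <- clamp(x - lam * step)
      fx_new <- tryCatch(f(x_new), error = function(e) rep(Inf, length(fx)))
      if (all(is.finite(fx_new)) &&
          max(abs(fx_new)) < max(abs(fx)) * (1 - 1e-4 * lam) + 1e-15) break
      lam <- lam / 2
      if (lam < 1e-6) break
    }
    if (max(abs(fx_new)) >= max(abs(fx)))
      return(list(x = x, fx = fx, converged = max(abs(fx)) < tol,
                  iterations = it))
    x <- x_new
    fx <- fx_new
  }
  list(x = x, fx = fx, converged = max(abs(fx)) < tol,
       iterations = max_iter)
}

#' Potentials of the population-averaged autocorrelation motion
#'
#' The autocorrelation dynamics are Newtonian: `C_K(tau)` moves in the
#' potential
#' \deqn{V_E = -\tfrac12 C_E^2 + g^2 a_E f_{\rho_E}(C_E, c_{E0})
#'   + g^2 b_E f_{\rho_I}(C_I, c_{I0})}
#' (and the I row with coefficients `a_I`, `b_I`), where `rho_K` is the
#' antiderivative of the transfer shifted by the stationary mean and
#' `a_E = N_E (1 + eta_E) / N`, `b_E = N_I / N`, `a_I = N_E / N`,
#' `b_I = N_I (1 + eta_I) / N`. The pairing of `rho` inside the Gaussian
#' pair expectation is fixed by Price's theorem, so that the `C`-derivative
#' of the potential reproduces the transfer pair expectation (see
#' [powers()]).
#'
#' @param params An [ei_params()] object.
#' @param C_E,C_I Autocorrelation values.
#' @param c_E0,c_I0 Variances.
#' @param means Stationary means `c(mean_E, mean_I)`.
#' @return Named vector `c(V_E, V_I)`.
#' @export
potentials <- function(params, C_E, C_I, c_E0, c_I0, means = c(0, 0)) {
  if (params$g == 0)
    return(c(V_E = -C_E^2 / 2, V_I = -C_I^2 / 2))
  k <- kernel_coefs(params)
  g2 <- params$g^2
  frE <- f_rho(params$transfer, C_E, c_E0, means[1])
  frI <- f_rho(params$transfer, C_I, c_I0, means[2])
  c(V_E = -C_E^2 / 2 + g2 * (k$a_E * frE + k$b_E * frI),
    V_I = -C_I^2 / 2 + g2 * (k$a_I * frE + k$b_I * frI))
}

#' Powers (dissipation functions) of the autocorrelation motion
#'
#' `W_K` is minus the total `C`-directional derivative of the potential
#' `V_K`:
#' \deqn{W_E = C_E - g^2 a_E f_{\phi_E}(C_E, c_{E0})
#'   - g^2 b_E f_{\phi_I}(C_I, c_{I0})}
#' (and the I row). `W_K` is also the right-hand side of the second-order
#' autocorrelation dynamics for positive lags, and its vanishing at the
#' long-lag limits is the dissipation condition that closes the
#' self-consistency system.
#'
#' @inheritParams potentials
#' @return Named vector `c(W_E, W_I)`.
#' @export
powers <- function(params, C_E, C_I, c_E0, c_I0, means = c(0, 0)) {
  if (params$g == 0) return(c(W_E = C_E, W_I = C_I))
  k <- kernel_coefs(params)
  g2 <- params$g^2
  fpE <- f_phi(params$transfer, C_E, c_E0, means[1])
  fpI <- f_phi(params$transfer, C_I, c_I0, means[2])
  c(W_E = C_E - g2 * (k$a_E * fpE + k$b_E * fpI),
    W_I = C_I - g2 * (k$a_I * fpE + k$b_I * fpI))
}

#' Solve the mean-field self-consistency system
#'
#' Determines the six stationary scalars of the reduced two-population
#' theory: the means `(mean_E, mean_I)`, the variances `(c_E0, c_I0)` and
#' the long-lag limits `(c_Einf, c_Iinf)`, satisfying simultaneously
#' (a) the stationary-mean equations, (b) the energy balance
#' `sigma^4/8 + V_K(c_E0, c_I0; .) = V_K(c_Einf, c_Iinf; .)` (the white
#' noise contributes kinetic energy `sigma^4/8` at lag 0), and (c) the
#' dissipation conditions `W_K(c_Einf, c_Iinf; .) = 0`.
#'
#' Structure: an outer damped Newton iteration on `(c_E0, c_I0)` (initialized
#' at the noise-only value `sigma^2/2`), with inner solves for the means and
#' for the long-lag limits at each candidate variance pair. For an odd
#' transfer the means are zero and `C = 0` solves the dissipation condition
#' exactly, so `c_Kinf = 0` on that branch. With `sigma = 0` the trivial
#' solution `c_K0 = 0` always exists; the solver then looks for a nonzero
#' (chaotic-branch) root as well, returns it when found, and records both.
#'
#' @param params An [ei_params()] object.
#' @param tol Residual tolerance (default 1e-10).
#' @param init Optional starting `(c_E0, c_I0)`.
#' @return An `ei_meanfield` object with fields `mean_E`, `mean_I`, `c_E0`,
#'   `c_I0`, `c_Einf`, `c_Iinf`, `converged`, `residuals` (named: means,
#'   energy, power), `branch` (`"noisy"`, `"zero"`, or `"chaotic"`), and
#'   `alt_roots`.
#' @examples
#' sol <- solve_self_consistency(ei_preset("fig2a"))
#' c(sol$c_E0, sol$c_Einf)
#' @export
solve_self_consistency <- function(params, tol = 1e-10, init = NULL) {
  spec <- params$transfer
  sigma <- params$sigma

  means_of <- function(c0) stationary_means(params, c0[1], c0[2])

  cinf_of <- function(c0, means) {
    if (spec$is_odd && all(abs(means) < 1e-12)) {
      # C = 0 solves W = 0 exactly for odd transfer, zero means
      return(c(0, 0))
    }
    # damped fixed point C <- g^2 (a f_phi + b f_phi), then Newton polish
    k <- kernel_coefs(params)
    g2 <- params$g^2
    Cc <- 0.9 * c0
    for (i in 1:200) {
      fpE <- f_phi(spec, Cc[1], c0[1], means[1])
      fpI <- f_phi(spec, Cc[2], c0[2], means[2])
      Cn <- c(g2 * (k$a_E * fpE + k$b_E * fpI),
              g2 * (k$a_I * fpE + k$b_I * fpI))
      Cn <- pmin(pmax(Cn, -c0), c0)
      if (max(abs(Cn - Cc)) < 1e-13) break
      Cc <- 0.5 * Cc + 0.5 * Cn
    }
    sol <- newton_system(
      function(Ci) powers(params, Ci[1], Ci[2], c0[1], c0[2], means),
      Cc, tol = 1e-12, lower = -c0, upper = c0)
    sol$x
  }

  resid_c0 <- function(c0) {
    mu <- means_of(c0)
    ci <- cinf_of(c0, mu)
    V0 <- potentials(params, c0[1], c0[2], c0[1], c0[2], mu)
    Vi <- potentials(params, ci[1], ci[2], c0[1], c0[2], mu)
    sigma^4 / 8 + V0 - Vi
  }

  # damped fixed point derived from the energy balance: writing (9) as
  # c0_K^2 / 2 = sigma^4/8 + g^2 [a (f_rho(c0) - f_rho(cinf)) + b (...)]
  # gives the update c0 <- sqrt(2 RHS(c0)); robust far from the root
  warm_start <- function(c0, n = 60) {
    for (i in seq_len(n)) {
      mu <- means_of(c0)
      ci <- cinf_of(c0, mu)
      V0 <- potentials(params, c0[1], c0[2], c0[1], c0[2], mu)
      Vi <- potentials(params, ci[1], ci[2], c0[1], c0[2], mu)
      rhs <- sigma^4 / 8 + (V0 + c0^2 / 2) - Vi
      c0_new <- sqrt(pmax(2 * rhs, 0))
      if (max(abs(c0_new - c0)) < 1e-12) break
      c0 <- 0.5 * c0 + 0.5 * c0_new
    }
    c0
  }

  zero_solution <- function() {
    mu <- means_of(c(0, 0))
    list(c0 = c(0, 0), cinf = c(0, 0), means = mu, branch = "zero")
  }

  solve_from <- function(start, scaled = FALSE) {
    # at sigma = 0 the residual vanishes quadratically at c0 = 0; dividing
    # by |c0|^2 removes that degenerate root so only a genuine chaotic
    # branch can be found
    f <- if (scaled) {
      function(c0) resid_c0(c0) / max(sum(c0^2), 1e-30)
    } else resid_c0
    sol <- newton_system(f, start, tol = tol, lower = c(1e-14, 1e-14))
    if (!sol$converged) return(NULL)
    c0 <- sol$x
    if (scaled && max(c0) < 1e-6) return(NULL)
    if (max(abs(resid_c0(c0))) > 1e-8) return(NULL)
    if (any(c0 < 1e-9)) c0 <- pmax(c0, 0)
    mu <- means_of(c0)
    list(c0 = c0, cinf = cinf_of(c0, mu), means = mu,
         branch = if (max(c0) < 1e-9) "zero"
                  else if (sigma > 0) "noisy" else "chaotic")
  }

  roots <- list()
  if (sigma > 0) {
    start <- if (is.null(init)) rep(sigma^2 / 2, 2) else init
    r <- solve_from(warm_start(start))
    if (is.null(r)) r <- solve_from(start)
    if (is.null(r)) r <- solve_from(warm_start(c(1, 1), n = 200))
    if (is.null(r))
      stop("self-consistency solve did not converge from the documented ",
           "initializations", call. = FALSE)
    roots <- list(r)
  } else {
    # the trivial branch is exact at sigma = 0; look for a chaotic branch
    roots <- list(zero_solution())
    for (start in list(init, c(0.5, 0.5), c(1.5, 1.5))) {
      if (is.null(start)) next
      r <- tryCatch(solve_from(start, scaled = TRUE),
                    error = function(e) NULL)
      if (!is.null(r) && r$branch == "chaotic") {
        roots <- c(list(r), roots)
        break
      }
    }
  }
  r <- roots[[1]]

  res_mean <- attr(r$means, "residual")
  res_energy <- resid_c0_value(params, r, sigma)
  res_power <- powers(params, r$cinf[1], r$cinf[2], r$c0[1], r$c0[2],
                      r$means)
  residuals <- c(means = unname(res_mean),
                 energy_E = unname(res_energy[1]),
                 energy_I = unname(res_energy[2]),
                 power_E = unname(res_power[1]),
                 power_I = unname(res_power[2]))
  structure(
    list(mean_E = unname(r$means[1]), mean_I = unname(r$means[2]),
         c_E0 = unname(r$c0[1]), c_I0 = unname(r$c0[2]),
         c_Einf = unname(r$cinf[1]), c_Iinf = unname(r$cinf[2]),
         converged = max(abs(residuals)) < 1e-8,
         residuals = residuals, branch = r$branch,
         alt_roots = if (length(roots) > 1) {
           lapply(roots[-1], function(z)
             c(c_E0 = z$c0[1], c_I0 = z$c0[2]))
         } else list(),
         params = params),
    class = "ei_meanfield"
  )
}

resid_c0_value <- function(params, r, sigma) {
  V0 <- potentials(params, r$c0[1], r$c0[2], r$c0[1], r$c0[2], r$means)
  Vi <- potentials(params, r$cinf[1], r$cinf[2], r$c0[1], r$c0[2], r$means)
  sigma^4 / 8 + V0 - Vi
}

#' @export
print.ei_meanfield <- function(x, ...) {
  cat("<ei_meanfield> branch:", x$branch,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  means: <x_E> = %.6g  <x_I> = %.6g\n", x$mean_E, x$mean_I))
  cat(sprintf("  c_E0 = %.6g  c_I0 = %.6g\n", x$c_E0, x$c_I0))
  cat(sprintf("  c_Einf = %.6g  c_Iinf = %.6g\n", x$c_Einf, x$c_Iinf))
  cat(sprintf("  max residual = %.3g\n", max(abs(x$residuals))))
  invisible(x)
}

#' Integrate the mean-field autocorrelation dynamics
#'
#' Solves the second-order lag dynamics of the autocorrelation pair for
#' `tau > 0`:
#' \deqn{\ddot C_K(\tau) = W_K(C_E, C_I; c_{E0}, c_{I0})}
#' from `C_K(0) = c_K0` with initial slope `C_K'(0+) = -sigma^2/2`. The
#' noise enters as a delta kick at zero lag, which appears here exactly as
#' the slope jump boundary condition (the decaying branch is taken so the
#' curve relaxes from `c_K0` toward `c_Kinf`; the growing branch is
#' unbounded). Integration uses `deSolve::lsodar` at tight tolerances with a
#' root function that stops the (dynamically unstable) lag dynamics when a
#' curve escapes `[-c_K0, c_K0]`.
#'
#' @param params An [ei_params()] object.
#' @param solution A converged [solve_self_consistency()] result.
#' @param tau_max Largest lag (default 10).
#' @param dtau Output grid step (default 0.01).
#' @param on_blowup `"error"` (default) to fail when the curve escapes
#'   before `tau_max`, or `"truncate"` to return the valid initial segment.
#' @return A tibble of class `ei_autocorr` with columns `tau`, `C_E`, `C_I`,
#'   `dC_E`, `dC_I`; attributes `c_E0`, `c_I0`, `provenance = "meanfield"`.
#' @export
integrate_autocorrelation <- function(params, solution, tau_max = 10,
                                      dtau = 0.01,
                                      on_blowup = c("error", "truncate")) {
  on_blowup <- match.arg(on_blowup)
  stopifnot(inherits(solution, "ei_meanfield"))
  if (!solution$converged)
    stop("`solution` must be a converged mean-field solution", call. = FALSE)
  c0 <- c(solution$c_E0, solution$c_I0)
  means <- c(solution$mean_E, solution$mean_I)
  margin <- 1e-6 + 1e-4 * max(c0)
  deriv <- function(t, y, parms) {
    # clamp trial states into the admissible covariance domain; real escapes
    # are caught by the root function
    CE <- min(max(y[1], -c0[1]), c0[1])
    CI <- min(max(y[3], -c0[2]), c0[2])
    W <- powers(params, CE, CI, c0[1], c0[2], means)
    list(c(y[2], W[1], y[4], W[2]))
  }
  rootfun <- function(t, y, parms) {
    min(c0[1] + margin - abs(y[1]), c0[2] + margin - abs(y[3]))
  }
  y0 <- c(c0[1], -params$sigma^2 / 2, c0[2], -params$sigma^2 / 2)
  taus <- seq(0, tau_max, by = dtau)
  out <- deSolve::lsodar(y = y0, times = taus, func = deriv, parms = NULL,
                         rtol = 1e-11, atol = 1e-12, rootfunc = rootfun)
  got <- nrow(out)
  if (got < length(taus)) {
    if (on_blowup == "error")
      stop(sprintf(
        "autocorrelation dynamics escaped [-c0, c0] at tau = %.3f; the ",
        out[got, 1]), "(c_E0, c_I0) pair is likely inconsistent",
        call. = FALSE)
  }
  res <- tibble::tibble(tau = out[, 1], C_E = out[, 2], dC_E = out[, 3],
                        C_I = out[, 4], dC_I = out[, 5])
  # drop a possibly-escaped terminal root point under truncation
  if (got < length(taus) && got > 1) res <- res[seq_len(got - 1L), ]
  res <- res[, c("tau", "C_E", "C_I", "dC_E", "dC_I")]
  class(res) <- c("ei_autocorr", class(res))
  attr(res, "c_E0") <- c0[1]
  attr(res, "c_I0") <- c0[2]
  attr(res, "provenance") <- "meanfield"
  attr(res, "solution") <- solution
  res
}

#' Energy-conservation residual of an autocorrelation curve
#'
#' The lag dynamics conserve the mechanical energy
#' `E_K(tau) = (1/2) C_K'(tau)^2 + V_K(C_E(tau), C_I(tau); c_E0, c_I0)`,
#' whose lag-0+ value is `sigma^4/8 + V_K(c_E0, c_I0)` (the white noise
#' contributes the initial kinetic energy). This function reports
#' `|E_K(tau) - E_K(0+)|` per lag with `C_K'` estimated by central
#' differences on the curve's grid.
#'
#' @param curve An [integrate_autocorrelation()] result.
#' @param params An [ei_params()] object.
#' @param solution The matching mean-field solution.
#' @return A tibble with columns `tau`, `res_E`, `res_I` (interior grid
#'   points only).
#' @export
energy_residual <- function(curve, params, solution) {
  stopifnot(inherits(curve, "ei_autocorr"))
  c0 <- c(solution$c_E0, solution$c_I0)
  means <- c(solution$mean_E, solution$mean_I)
  n <- nrow(curve)
  if (n < 3) stop("curve too short", call. = FALSE)
  h <- curve$tau[2] - curve$tau[1]
  interior <- 2:(n - 1)
  dE <- (curve$C_E[interior + 1] - curve$C_E[interior - 1]) / (2 * h)
  dI <- (curve$C_I[interior + 1] - curve$C_I[interior - 1]) / (2 * h)
  V <- vapply(interior, function(i) {
    potentials(params,
               min(max(curve$C_E[i], -c0[1]), c0[1]),
               min(max(curve$C_I[i], -c0[2]), c0[2]),
               c0[1], c0[2], means)
  }, numeric(2))
  V0 <- potentials(params, c0[1], c0[2], c0[1], c0[2], means)
  refE <- params$sigma^4 / 8 + V0[1]
  refI <- params$sigma^4 / 8 + V0[2]
  tibble::tibble(tau = curve$tau[interior],
                 res_E = abs(dE^2 / 2 + V[1, ] - refE),
                 res_I = abs(dI^2 / 2 + V[2, ] - refI))
}

#' Effective-noise (gamma) correlation kernel
#'
#' The mean-field reduction replaces the recurrent input by per-population
#' stationary Gaussian processes `gamma_K(t)` whose lag correlations are
#' \deqn{\kappa_E(\tau) = \frac{g^2}{N}\left[N_E(1+\eta_E)
#'   f_{\phi_E}(C_E(\tau), c_{E0}) + N_I f_{\phi_I}(C_I(\tau),
#'   c_{I0})\right]}
#' (and the I row with `(1 + eta_I)` on the inhibitory term). The kernel is
#' even in `tau` because the autocorrelations are.
#'
#' @param params An [ei_params()] object.
#' @param curve An `ei_autocorr` curve.
#' @param solution The matching mean-field solution.
#' @return A tibble of class `ei_gamma_kernel` with columns `tau`,
#'   `kappa_E`, `kappa_I`.
#' @export
gamma_kernel <- function(params, curve, solution) {
  stopifnot(inherits(curve, "ei_autocorr"))
  c0 <- c(solution$c_E0, solution$c_I0)
  means <- c(solution$mean_E, solution$mean_I)
  k <- kernel_coefs(params)
  g2 <- params$g^2
  fpE <- vapply(curve$C_E, function(C)
    f_phi(params$transfer, min(max(C, -c0[1]), c0[1]), c0[1], means[1]),
    numeric(1))
  fpI <- vapply(curve$C_I, function(C)
    f_phi(params$transfer, min(max(C, -c0[2]), c0[2]), c0[2], means[2]),
    numeric(1))
  out <- tibble::tibble(tau = curve$tau,
                        kappa_E = g2 * (k$a_E * fpE + k$b_E * fpI),
                        kappa_I = g2 * (k$a_I * fpE + k$b_I * fpI))
  class(out) <- c("ei_gamma_kernel", class(out))
  out
}

#' Synchronization conditions for the two populations
#'
#' Checks the three sufficient conditions under which the two populations
#' share one autocorrelation function (`C_E == C_I` at every lag):
#' (i) all couplings independent, `eta_E = eta_I = 0`;
#' (ii) odd transfer function and `N_E eta_E = N_I eta_I`;
#' (iii) equal stationary means with `N_E eta_E = N_I eta_I`.
#'
#' @param params An [ei_params()] object.
#' @param means Optional stationary means; computed from the self-consistency
#'   solution when needed (condition iii with a non-odd transfer).
#' @return Named logical vector `c(cond_i, cond_ii, cond_iii)` with attribute
#'   `any`.
#' @export
check_synchronization_conditions <- function(params, means = NULL) {
  tol <- 1e-10
  balanced <- abs(params$N_E * params$eta_E - params$N_I * params$eta_I) <
    tol * max(1, abs(params$N_E * params$eta_E))
  cond_i <- abs(params$eta_E) < tol && abs(params$eta_I) < tol
  cond_ii <- params$transfer$is_odd && balanced
  if (balanced) {
    if (is.null(means)) {
      means <- if (params$transfer$is_odd) c(0, 0) else {
        sol <- solve_self_consistency(params)
        c(sol$mean_E, sol$mean_I)
      }
    }
    cond_iii <- abs(means[1] - means[2]) < 1e-8
  } else {
    cond_iii <- FALSE
  }
  out <- c(cond_i = cond_i, cond_ii = cond_ii, cond_iii = unname(cond_iii))
  attr(out, "any") <- any(out)
  out
}
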