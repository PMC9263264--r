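#' @title Network integration (Euler-Maruyama)
#' @description Integrates the network Langevin dynamics
#'   \deqn{\dot x_i = -x_i + \sum_j J_{ij}\,\phi(x_j) + \sigma \xi_i(t)}
#'   with an Euler-Maruyama step: `x <- x + dt * (-x + J phi(x)) +
#'   sigma * sqrt(dt) * z`, `z` standard normal per neuron and step.
#'   The path is a pure function of `(params, J, x0, seed)`.
#'
#' @param params An [ei_params()] object.
#' @param J An [sample_coupling()] result (its `g` must match `params$g`
#'   conceptually; the matrix is used as given).
#' @param x0 Initial state vector of length `N` (E neurons first), or `NULL`
#'   to draw standard-normal initial conditions from the same seed.
#' @param t_end Integration horizon (units of the leak time constant).
#' @param dt Time step (default 0.01).
#' @param seed Integer seed for initial conditions and noise.
#' @param record_every Record the state every this many steps (default 10,
#'   i.e. a recorded resolution of `10 * dt`).
#' @return An `ei_trajectory`: list with `times` (recorded grid), `X_E`
#'   (`N_E x T`), `X_I` (`N_I x T`), `dt`, `record_every`, `seed`, `params`.
#' @examples
#' p <- ei_preset("fig2a", N_E = 30, N_I = 20)
#' tr <- integrate_network(p, sample_coupling(p, 1), t_end = 5, seed = 1)
#' dim(tr$X_E)
#' @export
integrate_network <- function(params, J, x0 = NULL, t_end = 100, dt = 0.01,
                              seed = 1, record_every = 10L) {
  stopifnot(inherits(params, "ei_params"))
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (t_end < dt) stop("`t_end` must be at least `dt`", call. = FALSE)
  N <- params$N
  Jm <- as.matrix(J)
  stopifnot(nrow(Jm) == N, ncol(Jm) == N)
  set.seed(as.integer(seed))
  if (is.null(x0)) x0 <- stats::rnorm(N)
  if (length(x0) != N || !all(is.finite(x0)))
    stop("`x0` must be a finite vector of length N", call. = FALSE)
  run <- em_run(Jm, matrix(x0, ncol = 1), n_steps = round(t_end / dt),
                dt = dt, sigma = params$sigma,
                phifun = tf_fun(params$transfer),
                record_every = as.integer(record_every))
  new_trajectory(run, params, dt, record_every, seed)
}

new_trajectory <- function(run, params, dt, record_every, seed) {
  iE <- seq_len(params$N_E)
  iI <- params$N_E + seq_len(params$N_I)
  structure(
    list(times = run$times,
         X_E = run$states[iE, 1, , drop = TRUE],
         X_I = run$states[iI, 1, , drop = TRUE],
         dt = dt, record_every = as.integer(record_every),
         seed = as.integer(seed), params = params),
    class = "ei_trajectory"
  )
}

# Core Euler-Maruyama stepper. X is N x k (k replicas); when k > 1 the same
# noise increment vector is shared by all columns (replica construction).
# Divergence (|x| > 1e6 or non-finite) aborts with the offending step.
em_run <- function(Jm, X, n_steps, dt, sigma, phifun, record_every = 1L) {
  N <- nrow(X)
  k <- ncol(X)
  sq <- sigma * sqrt(dt)
  n_rec <- n_steps %/% record_every
  states <- array(NA_real_, dim = c(N, k, n_rec + 1L))
  states[, , 1L] <- X
  times <- seq(0, by = dt * record_every, length.out = n_rec + 1L)
  ri <- 1L
  for (s in seq_len(n_steps)) {
    drift <- Jm %*% phifun(X)
    X <- X + dt * (drift - X)
    if (sigma > 0) X <- X + sq * stats::rnorm(N)  # recycles across columns
    m <- max(abs(X))
    if (!is.finite(m) || m > 1e6)
      stop(sprintf("state diverged at step %d (t = %.3f): max|x| = %g",
                   s, s * dt, m), call. = FALSE)
    if (s %% record_every == 0L) {
      ri <- ri + 1L
      states[, , ri] <- X
    }
  }
  list(states = states, times = times, final = X)
}

#' @export
print.ei_trajectory <- function(x, ...) {
  cat(sprintf(
    "<ei_trajectory> N_E=%d N_I=%d, t in [0, %g], dt=%g (recorded every %d)\n",
    nrow(x$X_E), nrow(x$X_I), max(x$times), x$dt, x$record_every))
  invisible(x)
}

#' Integrate a shared-noise replica pair
#'
#' Runs two copies of the network with the identical coupling matrix and the
#' identical white-noise path, differing only in their initial conditions:
#' the second replica starts at `x0` plus an offset of magnitude `epsilon`
#' per neuron along an independent random sign direction, so the initial
#' population-mean squared distance is exactly `epsilon^2`. Exponential
#' growth of the replica distance diagnoses chaos.
#'
#' @inheritParams integrate_network
#' @param epsilon Non-negative per-neuron offset magnitude.
#' @return An `ei_replica_pair`: list with `traj1`, `traj2`
#'   (`ei_trajectory`), and `epsilon`.
#' @export
integrate_replica_pair <- function(params, J, x0 = NULL, epsilon = 1e-8,
                                   t_end = 60, dt = 0.01, seed = 1,
                                   record_every = 10L) {
  stopifnot(inherits(params, "ei_params"))
  if (epsilon < 0) stop("`epsilon` must be >= 0", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  N <- params$N
  Jm <- as.matrix(J)
  stopifnot(nrow(Jm) == N, ncol(Jm) == N)
  set.seed(as.integer(seed))
  if (is.null(x0)) x0 <- stats::rnorm(N)
  offset <- epsilon * sign(stats::rnorm(N))
  run <- em_run(Jm, cbind(x0, x0 + offset), n_steps = round(t_end / dt),
                dt = dt, sigma = params$sigma,
                phifun = tf_fun(params$transfer),
                record_every = as.integer(record_every))
  split1 <- list(states = run$states[, 1L, , drop = FALSE],
                 times = run$times)
  split2 <- list(states = run$states[, 2L, , drop = FALSE],
                 times = run$times)
  structure(
    list(traj1 = new_trajectory(split1, params, dt, record_every, seed),
         traj2 = new_trajectory(split2, params, dt, record_every, seed),
         epsilon = epsilon),
    class = "ei_replica_pair"
  )
}

#' Replica distance series
#'
#' Population-mean squared distances between the two replicas,
#' `d_K(t) = (1/N_K) sum_i (x1_Ki(t) - x2_Ki(t))^2`, evaluated at each
#' recorded time point.
#'
#' @param pair An [integrate_replica_pair()] result.
#' @return A tibble of class `ei_distance` with columns `time`, `d_E`, `d_I`.
#' @export
replica_distance <- function(pair) {
  stopifnot(inherits(pair, "ei_replica_pair"))
  dE <- colMeans((pair$traj1$X_E - pair$traj2$X_E)^2)
  dI <- colMeans((pair$traj1$X_I - pair$traj2$X_I)^2)
  out <- tibble::tibble(time = pair$traj1$times, d_E = dE, d_I = dI)
  class(out) <- c("ei_distance", class(out))
  attr(out, "epsilon") <- pair$epsilon
  out
}

#' Empirical population autocorrelation functions
#'
#' Estimates the stationary autocorrelations
#' `C_K(tau) = <dx_K(t) dx_K(t + tau)>` from a simulated trajectory, where
#' `dx_K = x_K - <x_K>` with the population-and-time mean taken over the
#' post-burn-in window, averaging over neurons and time origins. The lag-0
#' value is the population-time variance of the windowed data by
#' construction.
#'
#' @param traj An `ei_trajectory`.
#' @param burn_in Time discarded before the stationary window (default 50).
#' @param tau_max Largest lag to estimate (default 5).
#' @return A tibble of class `ei_autocorr` with columns `tau`, `C_E`, `C_I`;
#'   attributes `c_E0`, `c_I0`, `provenance = "empirical"`.
#' @export
empirical_autocorrelation <- function(traj, burn_in = 50, tau_max = 5) {
  stopifnot(inherits(traj, "ei_trajectory"))
  dt_rec <- traj$dt * traj$record_every
  t_end <- max(traj$times)
  if (burn_in + tau_max >= t_end)
    stop(sprintf(
      "window too short: need t_end > burn_in + tau_max = %g (have %g)",
      burn_in + tau_max, t_end), call. = FALSE)
  keep <- traj$times >= burn_in
  L <- floor(tau_max / dt_rec)
  acf_pop <- function(X) {
    Xw <- X[, keep, drop = FALSE]
    D <- Xw - mean(Xw)
    Tw <- ncol(D)
    vapply(0:L, function(l) {
      sum(D[, seq_len(Tw - l)] * D[, l + seq_len(Tw - l)]) /
        (nrow(D) * (Tw - l))
    }, numeric(1))
  }
  CE <- acf_pop(traj$X_E)
  CI <- acf_pop(traj$X_I)
  out <- tibble::tibble(tau = (0:L) * dt_rec, C_E = CE, C_I = CI)
  class(out) <- c("ei_autocorr", class(out))
  attr(out, "c_E0") <- CE[1]
  attr(out, "c_I0") <- CI[1]
  attr(out, "provenance") <- "empirical"
  out
}

#' Stationarity diagnostic for the simulated process
#'
#' Tracks the running estimate of `<dx_K(t) dx_K(t + tau)>` at a fixed lag as
#' a function of the window start, to check that the process has relaxed to
#' stationarity after the burn-in used by the estimators.
#'
#' @param traj An `ei_trajectory`.
#' @param tau Fixed lag (default 0: running variance).
#' @param window Width of the running window (default 20 time units).
#' @return A tibble with columns `t_start`, `C_E`, `C_I`.
#' @export
stationarity_diagnostic <- function(traj, tau = 0, window = 20) {
  stopifnot(inherits(traj, "ei_trajectory"))
  dt_rec <- traj$dt * traj$record_every
  l <- round(tau / dt_rec)
  w <- round(window / dt_rec)
  Tn <- length(traj$times)
  starts <- seq(1L, Tn - w - l, by = max(1L, w %/% 4L))
  run_est <- function(X) {
    vapply(starts, function(s) {
      idx <- s:(s + w - l)               # time origins inside the window
      mu <- mean(X[, s:(s + w)])
      mean((X[, idx, drop = FALSE] - mu) *
             (X[, idx + l, drop = FALSE] - mu))
    }, numeric(1))
  }
  tibble::tibble(t_start = traj$times[starts],
                 C_E = run_est(traj$X_E), C_I = run_est(traj$X_I))
}

#' Maximal Lyapunov exponent from shared-noise replica simulations
#'
#' For each seed: samples a coupling matrix, burns the network in to its
#' stationary regime, then forks a shared-noise replica pair offset by
#' `epsilon` and fits the exponential growth rate of the squared replica
#' distance. Because `d_K` is a squared distance the exponent is half the
#' log-slope. Estimates are averaged over seeds with a standard error.
#'
#' The fit uses the region after the alignment transient (`t >= fit_t_min`)
#' and before saturation (`d_K <= d_cap`); if the usable region is shorter
#' than five time units the cap is relaxed. A fit R-squared below 0.8 sets
#' `low_r2 = TRUE` (expected near the chaos transition where the slope is
#' about zero).
#'
#' The Benettin variant instead renormalizes the replica separation back to
#' magnitude `epsilon` every `benettin_interval` time units and averages the
#' per-interval log expansions, avoiding saturation deep in the chaotic
#' regime.
#'
#' @param params An [ei_params()] object.
#' @param g Optional gain override.
#' @param seeds Integer vector of seeds (one independent network per seed).
#' @param epsilon Initial per-neuron offset magnitude (default 1e-8).
#' @param t_burn Burn-in before forking the pair (default 20).
#' @param t_end Pair horizon used for the fit (default 60).
#' @param dt Step size (default 0.01).
#' @param method `"direct_fit"` or `"benettin"`.
#' @param fit_t_min,d_cap Fit-window controls, see Details.
#' @param benettin_interval Renormalization interval for the Benettin method.
#' @return An `ei_mle` object: list with `lambda_E`, `lambda_I`, `se_E`,
#'   `se_I`, `method`, `by_seed` (tibble of per-seed fits), `low_r2`.
#' @export
estimate_mle <- function(params, g = NULL, seeds = 1:3, epsilon = 1e-8,
                         t_burn = 20, t_end = 60, dt = 0.01,
                         method = c("direct_fit", "benettin"),
                         fit_t_min = 5, d_cap = 1e-3,
                         benettin_interval = 2) {
  method <- match.arg(method)
  params <- set_gain(params, g)
  if (length(seeds) < 1) stop("need at least one seed", call. = FALSE)
  rows <- purrr::map_dfr(seeds, function(sd) {
    J <- sample_coupling(params, seed = sd)
    burn <- integrate_network(params, J, t_end = t_burn, dt = dt,
                              seed = sd + 1L,
                              record_every = round(t_burn / dt))
    x_star <- c(burn$X_E[, ncol(burn$X_E)], burn$X_I[, ncol(burn$X_I)])
    if (method == "direct_fit") {
      pair <- integrate_replica_pair(params, J, x0 = x_star,
                                     epsilon = epsilon, t_end = t_end,
                                     dt = dt, seed = sd + 2L)
      d <- replica_distance(pair)
      fE <- fit_log_slope(d$time, d$d_E, fit_t_min, d_cap)
      fI <- fit_log_slope(d$time, d$d_I, fit_t_min, d_cap)
      tibble::tibble(seed = sd,
                     lambda_E = fE$slope / 2, lambda_I = fI$slope / 2,
                     r2_E = fE$r2, r2_I = fI$r2,
                     t_lo = fE$t_lo, t_hi = fE$t_hi)
    } else {
      ben <- benettin_rates(params, J, x_star, epsilon, t_end, dt,
                            seed = sd + 2L, interval = benettin_interval)
      tibble::tibble(seed = sd,
                     lambda_E = ben["lambda_E"], lambda_I = ben["lambda_I"],
                     r2_E = NA_real_, r2_I = NA_real_,
                     t_lo = 0, t_hi = t_end)
    }
  })
  n <- nrow(rows)
  se <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else 0
  structure(
    list(lambda_E = mean(rows$lambda_E), lambda_I = mean(rows$lambda_I),
         se_E = se(rows$lambda_E), se_I = se(rows$lambda_I),
         method = method, n_realizations = n, by_seed = rows,
         fit_window = c(rows$t_lo[1], rows$t_hi[1]),
         low_r2 = method == "direct_fit" &&
           any(pmin(rows$r2_E, rows$r2_I) < 0.8),
         g = params$g),
    class = "ei_mle"
  )
}

# least-squares slope of log d(t) on the usable (transient-free,
# pre-saturation) region. The lower cutoff keeps the fit above the
# double-precision cancellation floor: replica states are O(1), so their
# differences cannot be resolved much below ~1e-15 per neuron (d ~ 1e-30);
# decaying pairs flatten out there and would bias the slope.
fit_log_slope <- function(time, d, fit_t_min, d_cap, d_floor = 1e-27) {
  ok <- time >= fit_t_min & d > d_floor & is.finite(d)
  use <- ok & d <= d_cap
  if (sum(use) < 10 ||
      (any(use) && diff(range(time[use])) < 5)) use <- ok
  if (sum(use) < 3) use <- ok
  tt <- time[use]
  yy <- log(d[use])
  fit <- stats::lm.fit(cbind(1, tt), yy)
  slope <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / max(sum((yy - mean(yy))^2), 1e-300)
  list(slope = unname(slope), r2 = r2,
       t_lo = min(tt), t_hi = max(tt))
}

# Benettin renormalization: integrate the pair interval by interval, rescale
# the separation to magnitude epsilon (network-level RMS norm), accumulate
# the per-population log expansions. d is squared, hence the factor 1/2.
benettin_rates <- function(params, J, x0, epsilon, t_end, dt, seed,
                           interval) {
  N <- params$N
  iE <- seq_len(params$N_E)
  iI <- params$N_E + seq_len(params$N_I)
  Jm <- as.matrix(J)
  set.seed(as.integer(seed))
  delta0 <- epsilon * sign(stats::rnorm(N))
  X <- cbind(x0, x0 + delta0)
  n_int <- max(1L, floor(t_end / interval))
  steps <- round(interval / dt)
  logs_E <- logs_I <- numeric(n_int)
  for (i in seq_len(n_int)) {
    delta <- X[, 2] - X[, 1]
    d0_E <- mean(delta[iE]^2)
    d0_I <- mean(delta[iI]^2)
    run <- em_run(Jm, X, n_steps = steps, dt = dt, sigma = params$sigma,
                  phifun = tf_fun(params$transfer), record_every = steps)
    X <- run$final
    delta <- X[, 2] - X[, 1]
    logs_E[i] <- log(mean(delta[iE]^2) / d0_E)
    logs_I[i] <- log(mean(delta[iI]^2) / d0_I)
    rms <- sqrt(mean(delta^2))
    X[, 2] <- X[, 1] + delta * (epsilon / rms)
  }
  c(lambda_E = mean(logs_E) / (2 * interval),
    lambda_I = mean(logs_I) / (2 * interval))
}

#' @export
print.ei_mle <- function(x, ...) {
  cat(sprintf(
    "<ei_mle> g=%g  lambda_E = %.4f (SE %.4f)  lambda_I = %.4f (SE %.4f)\n",
    x$g, x$lambda_E, x$se_E, x$lambda_I, x$se_I))
  cat(sprintf("  method=%s, %d realization(s)%s\n", x$method,
              x$n_realizations,
              if (isTRUE(x$low_r2)) ", low-R2 fit flagged" else ""))
  invisible(x)
}
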