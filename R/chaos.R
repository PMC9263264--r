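#' Evolve the linearized cross-correlation field
#'
#' The leading-order deviation of the replica cross-correlation from the
#' stationary autocorrelation, `G_K(t, t')`, obeys
#' \deqn{(\partial_{t'} + 1)(\partial_t + 1) G_K =
#'   \frac{g^2}{N}\big[N_E(1 + \delta_{KE}\eta_E)
#'   f_{\phi'_E}(C_E(t - t'), c_{E0})\, G_E
#'   + N_I(1 + \delta_{KI}\eta_I) f_{\phi'_I}(C_I(t - t'), c_{I0})\,
#'   G_I\big].}
#' Its diagonal `G_K(t, t)` tracks the squared replica distance, so the
#' asymptotic exponential rate along the diagonal gives the mean-field
#' maximal Lyapunov exponent (half the rate; see [meanfield_mle()]).
#'
#' The field is evolved on a uniform `(t, t')` lattice from a unit impulse
#' at the origin with free-decay data `exp(-t)` on the axes. The two
#' first-order `(d/dt + 1)` factors are discretized so the homogeneous
#' contraction is exact over a cell:
#' `G[i+1, j+1] = e^{-h}(G[i, j+1] + G[i+1, j]) - e^{-2h} G[i, j] +
#' h^2 RHS[i, j]`. Rows are rescaled on the fly when the field grows, so
#' strongly chaotic parameters do not overflow; the diagonal is kept on a
#' log scale.
#'
#' @param params An [ei_params()] object.
#' @param solution A converged [solve_self_consistency()] result.
#' @param curve Optional `ei_autocorr` mean-field curve supplying
#'   `C_K(tau)`; computed (with truncation and `c_Kinf` padding at long
#'   lags) when `NULL`.
#' @param t_max Lattice extent (default 20 time units).
#' @param dt Lattice step (default 0.05).
#' @param fit_frac Fractions of the diagonal used for the rate fit
#'   (default `c(0.5, 0.95)`).
#' @return An `ei_gfield`: list with `t` (lattice axis), `log_diag_E`,
#'   `log_diag_I` (log of the diagonal), `rate_E`, `rate_I` (asymptotic
#'   diagonal rates), matrices `G_E`, `G_I` when no rescaling occurred
#'   (`NULL` otherwise), and the fit details.
#' @export
evolve_G <- function(params, solution, curve = NULL, t_max = 20, dt = 0.05,
                     fit_frac = c(0.5, 0.95)) {
  stopifnot(inherits(solution, "ei_meanfield"))
  M <- round(t_max / dt)
  if (M < 20) stop("lattice too small for rate extraction; increase t_max",
                   call. = FALSE)
  if (is.null(curve)) {
    curve <- integrate_autocorrelation(params, solution, tau_max = t_max,
                                       dtau = dt, on_blowup = "truncate")
  }
  c0 <- c(solution$c_E0, solution$c_I0)
  means <- c(solution$mean_E, solution$mean_I)
  cinf <- c(solution$c_Einf, solution$c_Iinf)
  # kernel values f_phi'(C_K(d * dt), c_K0) for lattice lag d, padded with
  # the long-lag limit beyond the available curve
  C_at <- function(col, k) {
    v <- rep(cinf[k], M + 1L)
    n_av <- min(M + 1L, nrow(curve))
    v[seq_len(n_av)] <- curve[[col]][seq_len(n_av)]
    pmin(pmax(v, -c0[k]), c0[k])
  }
  CE <- C_at("C_E", 1L)
  CI <- C_at("C_I", 2L)
  kE <- vapply(CE, function(C) f_phiprime(params$transfer, C, c0[1],
                                          means[1]), numeric(1))
  kI <- vapply(CI, function(C) f_phiprime(params$transfer, C, c0[2],
                                          means[2]), numeric(1))
  k <- kernel_coefs(params)
  g2 <- params$g^2
  eh <- exp(-dt)
  e2h <- exp(-2 * dt)
  h2 <- dt^2

  axis <- exp(-dt * (0:M))
  GE_prev <- axis                      # row i = 0 (t = 0), over j
  GI_prev <- axis
  log_scale_prev <- 0
  log_diag_E <- log_diag_I <- numeric(M + 1L)
  log_diag_E[1] <- log_diag_I[1] <- 0
  keep_full <- TRUE
  GE_full <- GI_full <- NULL
  store_E <- store_I <- matrix(NA_real_, M + 1L, M + 1L)
  store_E[1, ] <- axis
  store_I[1, ] <- axis
  rescaled <- FALSE

  for (i in seq_len(M)) {            # advance t index: row i-1 -> row i
    lagidx <- abs(i - 1L - (0:(M - 1L))) + 1L   # |t - t'| at source cells
    rhsE <- (g2 / params$N) *
      (params$N_E * (1 + params$eta_E) * kE[lagidx] * GE_prev[1:M] +
       params$N_I * kI[lagidx] * GI_prev[1:M])
    rhsI <- (g2 / params$N) *
      (params$N_E * kE[lagidx] * GE_prev[1:M] +
       params$N_I * (1 + params$eta_I) * kI[lagidx] * GI_prev[1:M])
    bE <- eh * GE_prev[2:(M + 1L)] - e2h * GE_prev[1:M] + h2 * rhsE
    bI <- eh * GI_prev[2:(M + 1L)] - e2h * GI_prev[1:M] + h2 * rhsI
    # boundary on the t' = 0 axis: free decay from the impulse
    g0E <- exp(-dt * i - log_scale_prev)
    g0I <- g0E
    GE_row <- c(g0E, stats::filter(bE, eh, method = "recursive",
                                   init = g0E))
    GI_row <- c(g0I, stats::filter(bI, eh, method = "recursive",
                                   init = g0I))
    scale <- max(abs(GE_row), abs(GI_row))
    log_scale <- log_scale_prev
    if (scale > 1e100) {
      GE_row <- GE_row / scale
      GI_row <- GI_row / scale
      log_scale <- log_scale + log(scale)
      rescaled <- TRUE
      keep_full <- FALSE
    }
    di <- i + 1L
    log_diag_E[di] <- log(abs(GE_row[di])) + log_scale
    log_diag_I[di] <- log(abs(GI_row[di])) + log_scale
    if (keep_full) {
      store_E[di, ] <- GE_row
      store_I[di, ] <- GI_row
    }
    GE_prev <- GE_row
    GI_prev <- GI_row
    log_scale_prev <- log_scale
  }
  tt <- dt * (0:M)
  lo <- max(2L, ceiling(fit_frac[1] * M))
  hi <- min(M + 1L, floor(fit_frac[2] * M))
  fit <- function(ld) {
    idx <- lo:hi
    cf <- stats::lm.fit(cbind(1, tt[idx]), ld[idx])$coefficients
    unname(cf[2])
  }
  if (keep_full) {
    GE_full <- store_E
    GI_full <- store_I
  }
  structure(
    list(t = tt, log_diag_E = log_diag_E, log_diag_I = log_diag_I,
         rate_E = fit(log_diag_E), rate_I = fit(log_diag_I),
         G_E = GE_full, G_I = GI_full, dt = dt,
         rescaled = rescaled, fit_window = tt[c(lo, hi)]),
    class = "ei_gfield"
  )
}

#' @export
print.ei_gfield <- function(x, ...) {
  cat(sprintf(
    "<ei_gfield> lattice t in [0, %g] (dt=%g), diagonal rates: E %.4f, I %.4f\n",
    max(x$t), x$dt, x$rate_E, x$rate_I))
  invisible(x)
}

#' Mean-field maximal Lyapunov exponents from the G field
#'
#' The squared replica distance is proportional to the diagonal of the
#' linearized cross-correlation field, so the per-population exponent is
#' half the asymptotic diagonal growth rate.
#'
#' @param field An [evolve_G()] result.
#' @return Named vector `c(lambda_E, lambda_I)`.
#' @export
meanfield_mle <- function(field) {
  stopifnot(inherits(field, "ei_gfield"))
  c(lambda_E = field$rate_E / 2, lambda_I = field$rate_I / 2)
}

#' Critical gain from the mean-field chaos condition
#'
#' Solves the implicit condition for the onset of chaos,
#' \deqn{c_{K0} - g_{K,c}^2\left(1 + \frac{N_K \eta_K}{N}\right)
#'   f_{\phi_K}(c_{K0}, c_{K0}) = 0,}
#' in `g`, with `c_K0` (and the stationary mean) recomputed from the
#' self-consistency system at every candidate gain. When the noise-free
#' solution sits on the trivial branch (`c_K0 = 0`) the exact small-variance
#' limit of the condition, `1 - g^2 (1 + N_K eta_K / N) \phi'(mu_K)^2`, is
#' used, which gives `g_c = 1` for the unit-slope odd transfer with
#' independent couplings.
#'
#' The condition is derived under the synchronization conditions (equal
#' autocorrelations across populations); when none of them holds the result
#' is still computed per population but flagged advisory.
#'
#' `variant = "phi_prime"` replaces the transfer pair expectation by the
#' derivative pair expectation `f_{\phi'}` in the condition, matching the
#' kernel of the linearized field dynamics; offered for sensitivity
#' analysis.
#'
#' @param params An [ei_params()] object (its `g` is ignored).
#' @param bracket Search interval in `g` (default `c(0.2, 4)`).
#' @param variant `"phi"` (condition exactly as stated, default) or
#'   `"phi_prime"`.
#' @param tol Root tolerance in `g` (default 1e-3).
#' @param allow_partial When `TRUE`, a population whose condition never
#'   changes sign on the bracket yields `NA` (with a warning) instead of an
#'   error; outside the synchronization conditions the per-population
#'   condition need not have a root.
#' @return An `ei_critical` object: list with `g_Ec`, `g_Ic`,
#'   `method = "eq_condition"`, `advisory`, `variant`, and the scan table.
#' @export
critical_g <- function(params, bracket = c(0.2, 4),
                       variant = c("phi", "phi_prime"), tol = 1e-3,
                       allow_partial = FALSE) {
  variant <- match.arg(variant)
  sync <- check_synchronization_conditions(params)
  fexp <- if (variant == "phi") f_phi else f_phiprime
  ratio_K <- c(E = 1 + params$N_E * params$eta_E / params$N,
               I = 1 + params$N_I * params$eta_I / params$N)
  cond_value <- function(g, K) {
    p <- set_gain(params, g)
    sol <- solve_self_consistency(p)
    c0 <- if (K == "E") sol$c_E0 else sol$c_I0
    mu <- if (K == "E") sol$mean_E else sol$mean_I
    if (c0 < 1e-8) {
      dmu <- if (variant == "phi") tf_deriv(params$transfer, mu) else NA
      if (variant == "phi") {
        1 - g^2 * ratio_K[[K]] * dmu^2
      } else {
        # same limit: f_phi'(0,0) -> phi'(mu)^2
        1 - g^2 * ratio_K[[K]] * tf_deriv(params$transfer, mu)^2
      }
    } else {
      c0 - g^2 * ratio_K[[K]] * fexp(params$transfer, c0, c0, mu)
    }
  }
  solve_K <- function(K) {
    gs <- seq(bracket[1], bracket[2], length.out = 9)
    vals <- vapply(gs, cond_value, numeric(1), K = K)
    sgn <- sign(vals)
    idx <- which(sgn[-1] != sgn[-length(sgn)])[1]
    if (is.na(idx) && allow_partial) {
      warning("no sign change of the chaos condition for population ", K,
              " on the bracket; returning NA", call. = FALSE)
      return(list(g = NA_real_,
                  scan = tibble::tibble(g = gs, value = vals,
                                        population = K)))
    }
    if (is.na(idx)) {
      stop(sprintf(
        "no sign change of the chaos condition for population %s in [%g, %g]; scan: %s",
        K, bracket[1], bracket[2],
        paste(sprintf("g=%.2f:%.3g", gs, vals), collapse = ", ")),
        call. = FALSE)
    }
    root <- stats::uniroot(cond_value, c(gs[idx], gs[idx + 1]), K = K,
                           tol = tol)
    list(g = root$root, scan = tibble::tibble(g = gs, value = vals,
                                              population = K))
  }
  ecE <- solve_K("E")
  ecI <- solve_K("I")
  structure(
    list(g_Ec = ecE$g, g_Ic = ecI$g, method = "eq_condition",
         variant = variant, advisory = !attr(sync, "any"),
         uncertainty = c(E = tol, I = tol),
         scan = dplyr::bind_rows(ecE$scan, ecI$scan)),
    class = "ei_critical"
  )
}

#' Critical gain from simulated Lyapunov-exponent crossings
#'
#' Estimates the maximal Lyapunov exponent of each population on a grid of
#' gains by shared-noise replica simulation ([estimate_mle()]) and locates
#' the gain at which each exponent crosses zero by linear interpolation
#' between the bracketing grid points. A bootstrap over seeds gives the
#' crossing uncertainty.
#'
#' @param params An [ei_params()] object (its `g` is swept).
#' @param g_grid Ordered gain grid, at least 3 points.
#' @param seeds Seeds, at least 2 for a bootstrap.
#' @param n_boot Bootstrap resamples (default 200).
#' @param ... Passed to [estimate_mle()] (e.g. `t_end`, `epsilon`,
#'   `N`-reduced params are set on `params` beforehand).
#' @return An `ei_critical` object with `g_Ec`, `g_Ic`,
#'   `method = "simulation_crossing"`, bootstrap `uncertainty`, and the
#'   per-gain exponent table `lambda_table`.
#' @export
simulation_critical_g <- function(params, g_grid, seeds = 1:3,
                                  n_boot = 200, ...) {
  if (length(g_grid) < 3 || is.unsorted(g_grid))
    stop("`g_grid` must be an ordered grid of at least 3 gains",
         call. = FALSE)
  fits <- purrr::map(g_grid, function(g)
    estimate_mle(params, g = g, seeds = seeds, ...))
  tab <- purrr::map2_dfr(fits, g_grid, function(f, g)
    dplyr::mutate(f$by_seed, g = g))
  lam <- tab |>
    dplyr::group_by(g) |>
    dplyr::summarise(lambda_E = mean(lambda_E), lambda_I = mean(lambda_I),
                     .groups = "drop")
  cross <- function(lambda) {
    sgn <- sign(lambda)
    idx <- which(sgn[-1] > 0 & sgn[-length(sgn)] <= 0)
    if (length(idx) == 0)
      stop("no zero crossing of the exponent on the gain grid; lambda = ",
           paste(sprintf("%.4f", lambda), collapse = ", "), call. = FALSE)
    i <- idx[1]
    g_grid[i] + (0 - lambda[i]) * (g_grid[i + 1] - g_grid[i]) /
      (lambda[i + 1] - lambda[i])
  }
  g_Ec <- cross(lam$lambda_E)
  g_Ic <- cross(lam$lambda_I)
  boot_one <- function(col) {
    reps <- vapply(seq_len(n_boot), function(b) {
      res <- tab |>
        dplyr::group_by(g) |>
        dplyr::slice_sample(n = length(seeds), replace = TRUE) |>
        dplyr::summarise(l = mean(.data[[col]]), .groups = "drop")
      tryCatch(cross(res$l), error = function(e) NA_real_)
    }, numeric(1))
    stats::sd(reps, na.rm = TRUE)
  }
  unc <- if (length(seeds) >= 2 && n_boot > 0) {
    c(E = boot_one("lambda_E"), I = boot_one("lambda_I"))
  } else c(E = NA_real_, I = NA_real_)
  structure(
    list(g_Ec = g_Ec, g_Ic = g_Ic, method = "simulation_crossing",
         advisory = FALSE, uncertainty = unc, lambda_table = lam,
         by_seed = tab),
    class = "ei_critical"
  )
}

#' Critical gain from the linearized-field diagonal rate
#'
#' Sweeps the gain, evolves the linearized cross-correlation field at each
#' value, and interpolates the gain at which the diagonal growth rate (hence
#' the mean-field exponent) crosses zero.
#'
#' @param params An [ei_params()] object.
#' @param g_grid Ordered gain grid, at least 3 points.
#' @param ... Passed to [evolve_G()].
#' @return An `ei_critical` object with `method = "gfield_crossing"`.
#' @export
gfield_critical_g <- function(params, g_grid, ...) {
  if (length(g_grid) < 3 || is.unsorted(g_grid))
    stop("`g_grid` must be an ordered grid of at least 3 gains",
         call. = FALSE)
  lam <- purrr::map_dfr(g_grid, function(g) {
    p <- set_gain(params, g)
    sol <- solve_self_consistency(p)
    fld <- evolve_G(p, sol, ...)
    mle <- meanfield_mle(fld)
    tibble::tibble(g = g, lambda_E = mle[["lambda_E"]],
                   lambda_I = mle[["lambda_I"]])
  })
  cross <- function(lambda) {
    sgn <- sign(lambda)
    idx <- which(sgn[-1] > 0 & sgn[-length(sgn)] <= 0)
    if (length(idx) == 0)
      stop("no zero crossing of the mean-field exponent on the grid",
           call. = FALSE)
    i <- idx[1]
    g_grid[i] - lambda[i] * (g_grid[i + 1] - g_grid[i]) /
      (lambda[i + 1] - lambda[i])
  }
  structure(
    list(g_Ec = cross(lam$lambda_E), g_Ic = cross(lam$lambda_I),
         method = "gfield_crossing", advisory = FALSE,
         uncertainty = c(E = NA_real_, I = NA_real_), lambda_table = lam),
    class = "ei_critical"
  )
}

#' @export
print.ei_critical <- function(x, ...) {
  cat(sprintf("<ei_critical> method=%s%s\n", x$method,
              if (isTRUE(x$advisory)) " (advisory)" else ""))
  cat(sprintf("  g_Ec = %.4f  g_Ic = %.4f\n", x$g_Ec, x$g_Ic))
  if (!all(is.na(x$uncertainty)))
    cat(sprintf("  uncertainty: E %.3g, I %.3g\n",
                x$uncertainty[1], x$uncertainty[2]))
  invisible(x)
}
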