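#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a mean-field solution
#'
#' @param x An `ei_meanfield` object.
#' @param ... Unused.
#' @return A tibble with one row per solved scalar (`term`, `estimate`).
#' @method tidy ei_meanfield
#' @export
tidy.ei_meanfield <- function(x, ...) {
  tibble::tibble(
    term = c("mean_E", "mean_I", "c_E0", "c_I0", "c_Einf", "c_Iinf"),
    estimate = c(x$mean_E, x$mean_I, x$c_E0, x$c_I0, x$c_Einf, x$c_Iinf))
}

#' @rdname tidy.ei_meanfield
#' @method glance ei_meanfield
#' @export
glance.ei_meanfield <- function(x, ...) {
  tibble::tibble(converged = x$converged, branch = x$branch,
                 max_residual = max(abs(x$residuals)),
                 n_alt_roots = length(x$alt_roots))
}

#' Tidy a Lyapunov-exponent estimate
#'
#' @param x An `ei_mle` object.
#' @param ... Unused.
#' @return One row per population with `estimate` and `std.error`.
#' @method tidy ei_mle
#' @export
tidy.ei_mle <- function(x, ...) {
  tibble::tibble(term = c("lambda_E", "lambda_I"),
                 estimate = c(x$lambda_E, x$lambda_I),
                 std.error = c(x$se_E, x$se_I))
}

#' @rdname tidy.ei_mle
#' @method glance ei_mle
#' @export
glance.ei_mle <- function(x, ...) {
  tibble::tibble(g = x$g, method = x$method,
                 n_realizations = x$n_realizations,
                 low_r2 = isTRUE(x$low_r2))
}

#' Tidy a critical-gain result
#'
#' @param x An `ei_critical` object.
#' @param ... Unused.
#' @return One row per population with the critical gain and uncertainty.
#' @method tidy ei_critical
#' @export
tidy.ei_critical <- function(x, ...) {
  tibble::tibble(population = c("E", "I"),
                 g_c = c(x$g_Ec, x$g_Ic),
                 uncertainty = as.numeric(x$uncertainty))
}

#' @rdname tidy.ei_critical
#' @method glance ei_critical
#' @export
glance.ei_critical <- function(x, ...) {
  tibble::tibble(method = x$method, advisory = isTRUE(x$advisory))
}

#' Tidy a stability sweep
#'
#' @param x An `ei_stability` tibble (from [stability_sweep()]).
#' @param ... Unused.
#' @return The per-gain summary: `g`, `rho_mean`, `rho_sd`.
#' @method tidy ei_stability
#' @export
tidy.ei_stability <- function(x, ...) attr(x, "summary")

#' @rdname tidy.ei_stability
#' @method glance ei_stability
#' @export
glance.ei_stability <- function(x, ...) {
  tibble::tibble(crossing = attr(x, "crossing"),
                 reference = attr(x, "reference"),
                 n_gains = length(unique(x$g)))
}
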