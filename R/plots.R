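#' Plot autocorrelation curves
#'
#' @param object An `ei_autocorr` tibble (mean-field or empirical).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ei_autocorr
#' @export
autoplot.ei_autocorr <- function(object, ...) {
  long <- tidyr::pivot_longer(object[, c("tau", "C_E", "C_I")],
                              c("C_E", "C_I"),
                              names_to = "population", values_to = "C")
  ggplot2::ggplot(long, ggplot2::aes(.data$tau, .data$C,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(tau), y = expression(C[K](tau)),
                  colour = NULL,
                  subtitle = paste0(attr(object, "provenance"),
                                    " autocorrelation")) +
    ggplot2::theme_minimal()
}

#' Plot a replica-distance series
#'
#' @param object An `ei_distance` tibble.
#' @param ... Unused.
#' @return A ggplot with a log-scaled distance axis.
#' @method autoplot ei_distance
#' @export
autoplot.ei_distance <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("d_E", "d_I"),
                              names_to = "population", values_to = "d")
  long <- dplyr::filter(long, .data$d > 0)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$d,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "t", y = expression(d[K](t)), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a stability sweep
#'
#' @param object An `ei_stability` tibble.
#' @param ... Unused.
#' @return A ggplot of the spectral abscissa against the gain.
#' @method autoplot ei_stability
#' @export
autoplot.ei_stability <- function(object, ...) {
  summ <- attr(object, "summary")
  ggplot2::ggplot(summ, ggplot2::aes(.data$g, .data$rho_mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$rho_mean - .data$rho_sd,
      ymax = .data$rho_mean + .data$rho_sd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "g", y = expression(rho)) +
    ggplot2::theme_minimal()
}

#' Plot per-gain Lyapunov exponents of a critical-gain search
#'
#' @param object An `ei_critical` object carrying a `lambda_table`.
#' @param ... Unused.
#' @return A ggplot of the exponents against the gain.
#' @method autoplot ei_critical
#' @export
autoplot.ei_critical <- function(object, ...) {
  if (is.null(object$lambda_table))
    stop("this critical-gain result carries no lambda(g) table",
         call. = FALSE)
  long <- tidyr::pivot_longer(object$lambda_table,
                              c("lambda_E", "lambda_I"),
                              names_to = "population",
                              values_to = "lambda")
  ggplot2::ggplot(long, ggplot2::aes(.data$g, .data$lambda,
                                     colour = .data$population)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(object$g_Ec, object$g_Ic),
                        linetype = 3) +
    ggplot2::labs(x = "g", y = expression(lambda[max]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
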