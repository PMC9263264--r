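#' Transfer-function specification
#'
#' The network nonlinearity is an arctangent or one of its two variants:
#' `"atan"` is \eqn{\phi(x) = \arctan x}; `"scaled_atan"` is
#' \eqn{\phi_a(x) = \arctan(ax)} with slope parameter `a > 0` at the origin;
#' `"relu_atan"` is the rectified, non-odd variant
#' \eqn{\phi(x) = \max(\arctan x, 0)}.
#'
#' Whether the function is odd matters downstream: for odd transfer functions
#' the stationary population means vanish and the long-lag autocorrelation
#' limits are zero.
#'
#' @param name One of `"atan"`, `"scaled_atan"`, `"relu_atan"`.
#' @param slope Positive slope parameter `a`; only used by `"scaled_atan"`.
#' @return An object of class `ei_transfer` with fields `name`, `slope`,
#'   `is_odd`.
#' @examples
#' tf <- transfer_spec("scaled_atan", slope = 2)
#' transfer_eval(tf, 0.5, "derivative")
#' @export
transfer_spec <- function(name = c("atan", "scaled_atan", "relu_atan"),
                          slope = 1) {
  name <- match.arg(name)
  if (name == "scaled_atan") {
    if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope) ||
        slope <= 0) {
      stop("`slope` must be a positive finite scalar for 'scaled_atan'",
           call. = FALSE)
    }
  } else {
    slope <- 1
  }
  structure(
    list(name = name, slope = slope,
         is_odd = name %in% c("atan", "scaled_atan")),
    class = "ei_transfer"
  )
}

#' @export
print.ei_transfer <- function(x, ...) {
  lab <- switch(x$name,
    atan = "phi(x) = arctan(x)",
    scaled_atan = sprintf("phi(x) = arctan(%g x)", x$slope),
    relu_atan = "phi(x) = max(arctan(x), 0)")
  cat("<ei_transfer> ", lab, if (x$is_odd) " [odd]" else " [non-odd]", "\n",
      sep = "")
  invisible(x)
}

#' Evaluate a transfer function, its derivative, or its antiderivative
#'
#' All three orders are closed-form. The antiderivative is taken from zero,
#' \eqn{\Phi(x) = \int_0^x \phi(y)\,dy}; shifted potentials used by the
#' mean-field machinery apply offsets at the call site.
#'
#' @param spec An [transfer_spec()] object.
#' @param x Numeric vector of evaluation points.
#' @param order `"value"`, `"derivative"`, or `"antiderivative"`.
#' @return Numeric vector the same length as `x`.
#' @export
transfer_eval <- function(spec, x,
                          order = c("value", "derivative", "antiderivative")) {
  stopifnot(inherits(spec, "ei_transfer"))
  order <- match.arg(order)
  switch(order,
    value = tf_value(spec, x),
    derivative = tf_deriv(spec, x),
    antiderivative = tf_anti(spec, x))
}

tf_value <- function(spec, x) {
  switch(spec$name,
    atan = atan(x),
    scaled_atan = atan(spec$slope * x),
    relu_atan = pmax(atan(x), 0))
}

tf_deriv <- function(spec, x) {
  switch(spec$name,
    atan = 1 / (1 + x^2),
    scaled_atan = spec$slope / (1 + (spec$slope * x)^2),
    relu_atan = ifelse(x > 0, 1 / (1 + x^2), 0))
}

# int_0^x arctan(a y) dy = x atan(a x) - log(1 + a^2 x^2) / (2 a)
tf_anti <- function(spec, x) {
  switch(spec$name,
    atan = x * atan(x) - log1p(x^2) / 2,
    scaled_atan = x * atan(spec$slope * x) -
      log1p((spec$slope * x)^2) / (2 * spec$slope),
    relu_atan = ifelse(x > 0, x * atan(x) - log1p(x^2) / 2, 0))
}

# function handles, convenient for quadrature callers
tf_fun <- function(spec) function(x) tf_value(spec, x)
tf_dfun <- function(spec) function(x) tf_deriv(spec, x)
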