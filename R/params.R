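#' Model parameters for the two-population random network
#'
#' Bundles the full parameterization of the noise-driven excitatory-inhibitory
#' rate network: population sizes, the four mean-coupling scalars, the gain
#' `g` scaling the coupling fluctuations, the reciprocal-pair correlations
#' `eta_E`, `eta_I` inside each population, the white-noise intensity `sigma`,
#' and the transfer function.
#'
#' Couplings within population K are pairwise correlated: the reciprocal
#' weights (J_ij, J_ji) are bivariate normal with mean `m_KK / N_K`, variance
#' `g^2 / N` and correlation `eta_K`. Couplings between populations are
#' independent with mean `m_KL / N_L` and variance `g^2 / N`.
#'
#' @param N_E,N_I Population sizes (integers, at least 2).
#' @param m_EE,m_EI,m_IE,m_II Mean-coupling scalars. First index is the
#'   receiving population, second the sending one; `m_EI` is the mean drive
#'   from inhibitory onto excitatory neurons.
#' @param g Gain (non-negative): standard deviation of coupling fluctuations
#'   is `g / sqrt(N)`.
#' @param eta_E,eta_I Reciprocal-pair correlations, in `[-1, 1]`.
#' @param sigma White-noise intensity (non-negative).
#' @param transfer A [transfer_spec()] object.
#' @return An object of class `ei_params`.
#' @examples
#' p <- ei_params(N_E = 1500, N_I = 1000, m_EE = 1, m_EI = -0.25,
#'                m_IE = 0.75, m_II = -0.5, g = 1.4,
#'                eta_E = 1 / 3, eta_I = 1 / 2, sigma = 0.8)
#' p$N
#' @export
ei_params <- function(N_E, N_I, m_EE, m_EI, m_IE, m_II, g,
                      eta_E, eta_I, sigma,
                      transfer = transfer_spec("atan")) {
  chk_scalar <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("parameter `%s` must be a finite numeric scalar", nm),
           call. = FALSE)
    x
  }
  for (nm in c("N_E", "N_I", "m_EE", "m_EI", "m_IE", "m_II", "g",
               "eta_E", "eta_I", "sigma")) {
    chk_scalar(get(nm), nm)
  }
  if (N_E < 2 || N_E != round(N_E))
    stop("parameter `N_E` must be an integer >= 2", call. = FALSE)
  if (N_I < 2 || N_I != round(N_I))
    stop("parameter `N_I` must be an integer >= 2", call. = FALSE)
  if (abs(eta_E) > 1)
    stop("parameter `eta_E` must lie in [-1, 1]", call. = FALSE)
  if (abs(eta_I) > 1)
    stop("parameter `eta_I` must lie in [-1, 1]", call. = FALSE)
  if (g < 0) stop("parameter `g` must be >= 0", call. = FALSE)
  if (sigma < 0) stop("parameter `sigma` must be >= 0", call. = FALSE)
  if (!inherits(transfer, "ei_transfer"))
    stop("parameter `transfer` must be a transfer_spec() object",
         call. = FALSE)
  structure(
    list(N_E = as.integer(N_E), N_I = as.integer(N_I),
         N = as.integer(N_E + N_I),
         m_EE = m_EE, m_EI = m_EI, m_IE = m_IE, m_II = m_II,
         g = g, eta_E = eta_E, eta_I = eta_I, sigma = sigma,
         transfer = transfer),
    class = "ei_params"
  )
}

#' Build model parameters from a named mapping
#'
#' Validating constructor that takes a plain named list (for example parsed
#' from a YAML or JSON config). `transfer` may be a `transfer_spec()` object,
#' a name string, or a list with `name` and `slope`. Fractions given as
#' strings (`"1/3"`) are accepted for the numeric fields so configs can state
#' correlations exactly.
#'
#' @param raw Named list with entries `N_E`, `N_I`, `m_EE`, `m_EI`, `m_IE`,
#'   `m_II`, `g`, `eta_E`, `eta_I`, `sigma` and optionally `transfer`,
#'   `slope`.
#' @return An `ei_params` object.
#' @export
as_ei_params <- function(raw) {
  if (inherits(raw, "ei_params")) return(raw)
  stopifnot(is.list(raw))
  required <- c("N_E", "N_I", "m_EE", "m_EI", "m_IE", "m_II", "g",
                "eta_E", "eta_I", "sigma")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0)
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  num <- lapply(raw[required], parse_fraction)
  tf <- raw$transfer
  if (is.null(tf)) tf <- "atan"
  if (is.character(tf)) {
    tf <- transfer_spec(tf, slope = if (is.null(raw$slope)) 1
                        else parse_fraction(raw$slope))
  } else if (is.list(tf) && !inherits(tf, "ei_transfer")) {
    tf <- transfer_spec(tf$name,
                        slope = if (is.null(tf$slope)) 1
                        else parse_fraction(tf$slope))
  }
  do.call(ei_params, c(num, list(transfer = tf)))
}

# "1/3" -> 1/3; numbers pass through
parse_fraction <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (grepl("^\\s*-?[0-9.]+\\s*/\\s*-?[0-9.]+\\s*$", x)) {
      parts <- as.numeric(strsplit(x, "/")[[1]])
      return(parts[1] / parts[2])
    }
    v <- suppressWarnings(as.numeric(x))
    if (!is.na(v)) return(v)
  }
  stop("cannot interpret value as a number: ", deparse(x), call. = FALSE)
}

#' @export
print.ei_params <- function(x, ...) {
  cat(sprintf("<ei_params> N_E=%d N_I=%d (N=%d)\n", x$N_E, x$N_I, x$N))
  cat(sprintf("  means: m_EE=%g m_EI=%g m_IE=%g m_II=%g\n",
              x$m_EE, x$m_EI, x$m_IE, x$m_II))
  cat(sprintf("  g=%g  eta_E=%g  eta_I=%g  sigma=%g\n",
              x$g, x$eta_E, x$eta_I, x$sigma))
  print(x$transfer)
  invisible(x)
}

# convenience: copy of params with a different gain (used by all g sweeps)
set_gain <- function(params, g) {
  stopifnot(inherits(params, "ei_params"))
  if (is.null(g)) return(params)
  params$g <- g
  params
}

#' Named parameter presets
#'
#' Returns one of the parameter sets used throughout the package's worked
#' analyses, shipped as data in `inst/extdata/presets.yaml`. The baseline
#' (`"fig2a"`) is a network of 1500 excitatory and 1000 inhibitory neurons
#' with `m_EE = 1`, `m_IE = 0.75`, `m_EI = -0.25`, `m_II = -0.5`, `g = 1.4`,
#' `sigma = 0.8`, `eta_E = 1/3`, `eta_I = 1/2` and the odd arctan transfer,
#' so that `N_E eta_E = N_I eta_I = 500`. Other presets modify correlations,
#' means, or the transfer function.
#'
#' @param name Preset name; see `ei_preset_names()`.
#' @param ... Named overrides applied on top of the preset (e.g. `g = 2`,
#'   `N_E = 600`).
#' @return An `ei_params` object.
#' @examples
#' ei_preset("fig3b", g = 1.9)
#' @export
ei_preset <- function(name, ...) {
  presets <- load_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  raw <- presets[[name]]
  dots <- list(...)
  if (length(dots) > 0) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("preset overrides must be named", call. = FALSE)
    raw[names(dots)] <- dots
  }
  as_ei_params(raw)
}

#' @rdname ei_preset
#' @export
ei_preset_names <- function() names(load_presets())

load_presets <- function() {
  path <- system.file("extdata", "presets.yaml", package = "eidyn")
  if (path == "") path <- file.path("inst", "extdata", "presets.yaml")
  yaml::read_yaml(path)
}
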