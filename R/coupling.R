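#' Sample the correlated block coupling matrix
#'
#' Draws the full random connectivity of the two-population network. Within
#' each population K the reciprocal weights of every unordered pair (i, j),
#' i != j, are drawn jointly from a bivariate normal with mean `m_KK / N_K`,
#' variance `g^2 / N` and correlation `eta_K`; diagonal self-couplings are
#' drawn independently from the same marginal. Between populations every
#' entry is independent with mean `m_KL / N_L` (L the sending population) and
#' variance `g^2 / N`.
#'
#' The degenerate correlations are exact: at `eta_K = 1` the two reciprocal
#' weights are identical, at `eta_K = -1` they satisfy
#' `J_ji = -(J_ij - m) + m` with `m = m_KK / N_K`.
#'
#' Sampling is a pure function of `(params, seed)`: a single RNG stream is
#' seeded once and the blocks are drawn in the fixed order EE, EI, IE, II.
#'
#' @param params An [ei_params()] object.
#' @param seed Integer seed.
#' @return An object of class `ei_coupling`: list with blocks `J_EE`
#'   (`N_E x N_E`), `J_EI` (`N_E x N_I`), `J_IE`, `J_II`, plus `seed` and the
#'   block dimensions. Use [as.matrix()] to assemble the full `N x N` matrix
#'   (E rows/columns first).
#' @examples
#' J <- sample_coupling(ei_preset("fig2a", N_E = 20, N_I = 10), seed = 1)
#' dim(as.matrix(J))
#' @export
sample_coupling <- function(params, seed) {
  stopifnot(inherits(params, "ei_params"))
  if (length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  N <- params$N
  sd_all <- params$g / sqrt(N)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  J_EE <- intra_block(params$N_E, params$m_EE / params$N_E, sd_all,
                      params$eta_E)
  J_EI <- matrix(stats::rnorm(params$N_E * params$N_I,
                              mean = params$m_EI / params$N_I, sd = sd_all),
                 params$N_E, params$N_I)
  J_IE <- matrix(stats::rnorm(params$N_I * params$N_E,
                              mean = params$m_IE / params$N_E, sd = sd_all),
                 params$N_I, params$N_E)
  J_II <- intra_block(params$N_I, params$m_II / params$N_I, sd_all,
                      params$eta_I)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(
    list(J_EE = J_EE, J_EI = J_EI, J_IE = J_IE, J_II = J_II,
         N_E = params$N_E, N_I = params$N_I, seed = as.integer(seed)),
    class = "ei_coupling"
  )
}

# reciprocal pairs via the exact square-root construction:
# z1 = a u + b v, z2 = a u - b v with a = sqrt((1+eta)/2), b = sqrt((1-eta)/2)
# gives corr(z1, z2) = eta and unit variances, exactly degenerate at |eta|=1.
intra_block <- function(n, mean_kk, sd_all, eta) {
  a <- sqrt((1 + eta) / 2)
  b <- sqrt((1 - eta) / 2)
  np <- n * (n - 1) / 2
  u <- stats::rnorm(np)
  v <- stats::rnorm(np)
  upper <- upper.tri(matrix(0, n, n))
  Z <- matrix(0, n, n)
  Z[upper] <- a * u + b * v          # J[i, j], i < j
  Zl <- matrix(0, n, n)
  Zl[upper] <- a * u - b * v         # reciprocal J[j, i]
  Z <- Z + t(Zl)
  diag(Z) <- stats::rnorm(n)
  mean_kk + sd_all * Z
}

#' @export
as.matrix.ei_coupling <- function(x, ...) {
  rbind(cbind(x$J_EE, x$J_EI), cbind(x$J_IE, x$J_II))
}

#' @export
print.ei_coupling <- function(x, ...) {
  cat(sprintf("<ei_coupling> N_E=%d N_I=%d, seed=%d\n",
              x$N_E, x$N_I, x$seed))
  invisible(x)
}

#' Empirical block statistics of a sampled coupling matrix
#'
#' Summarizes each block of a sampled matrix: entry mean, entry variance, and
#' (for the intra-population blocks) the Pearson correlation over all
#' reciprocal off-diagonal pairs, with the diagonal excluded from all
#' intra-block statistics. Used to check the sampler against its targets.
#'
#' @param J An `ei_coupling` object.
#' @return A tibble with one row per block: `block`, `mean`, `var`,
#'   `pair_cor` (NA for inter-population blocks), `n_entries`.
#' @export
coupling_block_stats <- function(J) {
  stopifnot(inherits(J, "ei_coupling"))
  intra <- function(M) {
    up <- upper.tri(M)
    x <- M[up]
    y <- t(M)[up]
    off <- c(x, y)
    tibble::tibble(mean = mean(off), var = stats::var(off),
                   pair_cor = stats::cor(x, y), n_entries = length(off))
  }
  inter <- function(M) {
    tibble::tibble(mean = mean(M), var = stats::var(as.vector(M)),
                   pair_cor = NA_real_, n_entries = length(M))
  }
  dplyr::bind_rows(
    dplyr::mutate(intra(J$J_EE), block = "EE"),
    dplyr::mutate(inter(J$J_EI), block = "EI"),
    dplyr::mutate(inter(J$J_IE), block = "IE"),
    dplyr::mutate(intra(J$J_II), block = "II")
  )[, c("block", "mean", "var", "pair_cor", "n_entries")]
}
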