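#' Normalized Legendre polynomial covariates over days in milk
#'
#' Maps days in milk t to `x = 2 (t - t_min) / (t_max - t_min) - 1` on
#' `[-1, 1]` and evaluates the normalized Legendre polynomials
#' `phi_k(x) = sqrt((2k + 1) / 2) P_k(x)` for `k = 0..order`, with `P_k`
#' generated by the Bonnet recurrence.
#'
#' @param dim_values days-in-milk vector; every value must lie inside the
#'   window.
#' @param order polynomial order m >= 0.
#' @param dim_window closed window `c(t_min, t_max)`, default `c(8, 340)`.
#' @return numeric matrix, one row per record, columns `phi0..phim`.
#' @export
#' @examples
#' legendre_covariates(c(8, 174, 340), order = 2)
legendre_covariates <- function(dim_values, order, dim_window = c(8, 340)) {
  stopifnot(order >= 0)
  if (any(dim_values < dim_window[1] | dim_values > dim_window[2]))
    stop("days in milk outside the window [", dim_window[1], ", ",
         dim_window[2], "]", call. = FALSE)
  x <- 2 * (dim_values - dim_window[1]) / (dim_window[2] - dim_window[1]) - 1
  n <- length(x)
  P <- matrix(0, n, order + 1L)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- x
  if (order >= 2) {
    for (k in 2:order)  # Bonnet: k P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
  }
  phi <- sweep(P, 2L, sqrt((2 * seq(0, order) + 1) / 2), "*")
  colnames(phi) <- paste0("phi", seq(0, order))
  phi
}
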