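#' MCMC configuration
#'
#' Defaults match the study protocol: three parallel chains of 25,000
#' iterations, the first 5,000 discarded as burn-in, thinned by 10. The
#' number of retained draws per chain is `floor((n_iter - burn_in) / thin)`
#' (2,000 under the defaults). The master seed spawns one sub-stream per
#' chain so runs are reproducible per (config, seed).
#'
#' @param n_chains number of parallel chains.
#' @param n_iter iterations per chain.
#' @param burn_in discarded initial iterations (`< n_iter`).
#' @param thin keep every `thin`-th post-burn-in draw (`>= 1`).
#' @param seed integer master seed.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3L, n_iter = 25000L, burn_in = 5000L,
                        thin = 10L, seed = 1L) {
  stopifnot(burn_in < n_iter, thin >= 1L, n_chains >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf("mcmc_config: %d chain(s) x %d iterations (burn-in %d, thin %d)\n",
              x$n_chains, x$n_iter, x$burn_in, x$thin))
  cat("  retained draws per chain:", n_retained_draws(x), "\n")
  invisible(x)
}

#' @rdname mcmc_config
#' @param config an `mcmc_config`.
#' @export
n_retained_draws <- function(config) {
  (config$n_iter - config$burn_in) %/% config$thin
}

chain_seeds <- function(config) {
  set.seed(config$seed)
  sample.int(2^31 - 2, config$n_chains)
}

# scaled inverse-chi-square draw: (nu0*s0 + ss) / chisq(nu0 + n)
rinvchisq_post <- function(nu0, s0, ss, n) {
  (nu0 * s0 + ss) / rchisq(1L, nu0 + n)
}

# inverse-Wishart draw IW(df, S): invert a Wishart(df, S^-1) draw
rinvwishart <- function(df, S) {
  q <- nrow(S)
  if (q == 1L) return(matrix(S[1, 1] / rchisq(1L, df), 1, 1))
  W <- rWishart(1L, df, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}
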