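#' BayesR mixture-prior Gibbs sampler for SNP effects
#'
#' Whole-genome regression of one aggregated record per genotyped animal
#' (typically the per-animal mean adjusted test-day record) on centered
#' genotype dosages, under the four-component normal mixture prior on SNP
#' effects: class variances `(0, 1e-4, 1e-3, 1e-2) x sigma_g^2` by default,
#' with the first class exactly zero. Per iteration, every SNP's mixture
#' class is sampled from its posterior odds and its effect from the normal
#' full conditional (the inner sweep runs in compiled code); the mixture
#' proportions are updated from a Dirichlet full conditional, and
#' `sigma_g^2` and `sigma_e^2` from scaled inverse-chi-squares. An overall
#' mean with a flat prior is included.
#'
#' Per retained draw the sampler records the realized genomic variance
#' `Va = var(W beta)`, the residual variance `Ve`, `h2 = Va / (Va + Ve)`,
#' the mixture proportions and the non-null SNP count.
#'
#' @param y_bar one aggregated record per genotyped animal (fat %).
#' @param W centered genotype dosage matrix, animals x SNPs (e.g. calls
#'   minus twice the allele frequency); rownames must identify animals.
#' @param config an [mcmc_config()].
#' @param mixture_scales per-class effect-variance scales (fractions of
#'   `sigma_g^2`); length 4 expected, first entry 0. Other lengths are
#'   allowed with a warning.
#' @param update_pi sample the mixture proportions (set `FALSE` to keep
#'   `pi_init` fixed, e.g. to force a single non-null class).
#' @param pi_init initial/fixed mixture proportions.
#' @param priors optional overrides: `nu` (4), `s2_g0`, `s2_e0`
#'   (auto-scaled), `fixed` list with known `sigma2_g` and/or `sigma2_e`.
#' @return object of class `posterior_summary` with `coef_mean` (posterior
#'   mean SNP effects), `pip` (per-SNP posterior non-null probability) and
#'   mixture summaries.
#' @export
bayesr_snp_engine <- function(y_bar, W, config = mcmc_config(),
                              mixture_scales = c(0, 1e-4, 1e-3, 1e-2),
                              update_pi = TRUE,
                              pi_init = NULL,
                              priors = list()) {
  stopifnot(inherits(config, "mcmc_config"))
  W <- as.matrix(W)
  n <- nrow(W); p <- ncol(W)
  stopifnot(length(y_bar) == n)
  K <- length(mixture_scales)
  if (K != 4L)
    warning("mixture has ", K, " classes (4 is the standard configuration)")
  if (any(mixture_scales < 0))
    stop("mixture scales must be non-negative", call. = FALSE)
  if (mixture_scales[1] != 0)
    stop("the first mixture class must have scale 0 (null class)",
         call. = FALSE)
  if (is.null(pi_init)) pi_init <- rep(1 / K, K)
  stopifnot(length(pi_init) == K)

  vy <- max(var(y_bar), 1e-12)
  # sigma_g^2 is the total-genic-variance parameter: class-k effect
  # variance is mixture_scales[k] * sigma_g^2
  pr <- list(nu = 4, s2_g0 = 0.1 * vy, s2_e0 = 0.5 * vy, fixed = NULL)
  pr[names(priors)] <- priors
  fixed <- pr$fixed
  cj <- colSums(W^2)

  n_keep <- n_retained_draws(config)
  par_names <- c("mu", "Va", "Ve", "h2", "sigma2_g", "n_nonnull",
                 paste0("pi", seq_len(K)))
  chains <- vector("list", config$n_chains)
  beta_sum <- numeric(p)
  pip_sum <- numeric(p)
  seeds <- chain_seeds(config)

  for (ch in seq_len(config$n_chains)) {
    set.seed(seeds[ch])
    mu <- mean(y_bar)
    s2g <- if (!is.null(fixed$sigma2_g)) fixed$sigma2_g else 0.5 * vy
    s2e <- if (!is.null(fixed$sigma2_e)) fixed$sigma2_e else 0.5 * vy
    pi_k <- pi_init
    beta <- numeric(p)
    e <- y_bar - mu
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    kept <- 0L

    for (it in seq_len(config$n_iter)) {
      cls <- bayesr_sweep(W, e, beta, cj, mixture_scales * s2g,
                          log(pmax(pi_k, 1e-300)), s2e)
      counts <- tabulate(cls, K)
      if (update_pi) {
        g <- rgamma(K, shape = 1 + counts)
        pi_k <- g / sum(g)
      }
      nz <- beta != 0
      if (is.null(fixed$sigma2_g)) {
        ss_b <- sum(beta[nz]^2 / mixture_scales[cls[nz]])
        s2g <- rinvchisq_post(pr$nu, pr$s2_g0, ss_b, sum(nz))
      }
      # intercept and residual variance
      prec_mu <- n / s2e
      delta <- sum(e + mu) / n - mu
      mu_new <- mu + delta + rnorm(1) / sqrt(prec_mu)
      e <- e - (mu_new - mu)
      mu <- mu_new
      if (is.null(fixed$sigma2_e))
        s2e <- rinvchisq_post(pr$nu, pr$s2_e0, sum(e^2), n)

      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        g_hat <- drop(W %*% beta)
        Va <- var(g_hat)
        draws[kept, ] <- c(mu, Va, s2e, Va / (Va + s2e), s2g, sum(nz), pi_k)
        beta_sum <- beta_sum + beta
        pip_sum <- pip_sum + as.numeric(nz)
      }
    }
    chains[[ch]] <- draws
  }

  n_tot <- config$n_chains * n_keep
  coef_mean <- matrix(beta_sum / n_tot, ncol = 1,
                      dimnames = list(colnames(W), "beta"))
  out <- new_posterior_summary(
    engine = "bayesr", chains = chains, coef_mean = coef_mean,
    animal_ids = rownames(W), config = config,
    extra = list(pip = setNames(pip_sum / n_tot, colnames(W)),
                 mixture_scales = mixture_scales,
                 gebv_train = setNames(drop(W %*% (beta_sum / n_tot)),
                                       rownames(W))))
  out
}
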