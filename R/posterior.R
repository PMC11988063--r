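new_posterior_summary <- function(engine, chains, coef_mean, animal_ids,
                                  order = NULL, dim_window = NULL,
                                  config, extra = list()) {
  all_draws <- do.call(rbind, chains)
  structure(c(list(engine = engine, chains = chains,
                   coef_mean = coef_mean, animal_ids = animal_ids,
                   order = order, dim_window = dim_window, config = config,
                   means = colMeans(all_draws),
                   sds = apply(all_draws, 2L, sd),
                   n_draws_per_chain = nrow(chains[[1]])),
              extra),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary (%s): %d chain(s) x %d retained draws\n",
              x$engine, length(x$chains), x$n_draws_per_chain))
  keep <- intersect(c("Va", "Vpe", "Vherd", "Ve", "h2"), names(x$means))
  for (p in keep)
    cat(sprintf("  %-6s %8.4f +/- %.4f\n", p, x$means[[p]], x$sds[[p]]))
  invisible(x)
}

#' Heritability from variance components
#'
#' `h2 = Va / (Va + Ve)`: the fraction of phenotypic variance (here the sum
#' of additive genetic and residual variance) explained by additive
#' genetics. Vectorized, so it can be applied per MCMC draw; posterior mean
#' and SD are then reported from the draws.
#'
#' @param Va additive genetic variance (>= 0).
#' @param Ve residual variance (> 0 unless `Va > 0`).
#' @return heritability in `[0, 1]`.
#' @export
#' @examples
#' heritability(0.012, 0.106)  # 0.102, prints as 0.10
heritability <- function(Va, Ve) {
  if (any(Va < 0) || any(Ve < 0))
    stop("variance components must be non-negative", call. = FALSE)
  if (any(Va + Ve == 0))
    stop("heritability undefined when Va + Ve = 0", call. = FALSE)
  Va / (Va + Ve)
}

#' Extract retained draws of a parameter
#'
#' @param summary a `posterior_summary`.
#' @param parameter column name, e.g. `"h2"`, `"Va"`.
#' @return matrix draws x chains.
#' @export
posterior_draws <- function(summary, parameter) {
  stopifnot(inherits(summary, "posterior_summary"))
  sapply(summary$chains, function(d) d[, parameter])
}

#' Genomic-estimated breeding values from a posterior summary
#'
#' For the RR-GBLUP engine the GEBV is the additive genetic trajectory
#' `sum_k a_k phi_k(x(t))` averaged over the days-in-milk window (equal to
#' the rescaled intercept coefficient when the order is 0). For the BayesR
#' engine the GEBV is `W beta_hat` with `W` the centered genotypes; animals
#' without genotypes are excluded with a message.
#'
#' @param summary a `posterior_summary`.
#' @param genotypes a [genotype_matrix()]; required for the BayesR engine.
#' @return data.frame `animal_id`, `gebv` (fat %), sorted decreasing.
#' @export
gebv_from_posterior <- function(summary, genotypes = NULL) {
  stopifnot(inherits(summary, "posterior_summary"))
  if (summary$engine == "rr_gblup") {
    Pg <- legendre_covariates(seq(summary$dim_window[1],
                                  summary$dim_window[2]),
                              summary$order, summary$dim_window)
    traj_mean <- colMeans(Pg)
    gebv <- drop(summary$coef_mean %*% traj_mean)
    ids <- summary$animal_ids
  } else {
    if (is.null(genotypes)) {
      # training animals: linear score at the posterior-mean SNP effects
      ids <- summary$animal_ids
      gebv <- summary$gebv_train[ids]
    } else {
      ids <- intersect(summary$animal_ids, rownames(genotypes$calls))
      drop_ids <- setdiff(summary$animal_ids, ids)
      if (length(drop_ids))
        message(length(drop_ids), " animal(s) without genotypes excluded")
      M <- mean_imputer(subset_genotypes(
        genotypes, animals = match(ids, rownames(genotypes$calls))))$calls
      W <- sweep(M, 2L, colMeans(M))  # center on the panel's own mean dosage
      gebv <- drop(W %*% summary$coef_mean)
    }
  }
  out <- data.frame(animal_id = ids, gebv = unname(gebv),
                    stringsAsFactors = FALSE)
  out[order(-out$gebv), , drop = FALSE]
}

#' Summarize a GEBV table
#'
#' @param gebv data.frame from [gebv_from_posterior()] or a bare numeric
#'   vector of GEBVs (%).
#' @return named list `min`, `max`, `mean`.
#' @export
gebv_summary <- function(gebv) {
  v <- if (is.data.frame(gebv)) gebv$gebv else gebv
  list(min = min(v), max = max(v), mean = mean(v))
}

#' Write a GEBV table as tab-separated text
#' @param gebv data.frame from [gebv_from_posterior()].
#' @param path output path.
#' @export
write_gebv <- function(gebv, path) {
  out <- data.frame(AnimalID = gebv$animal_id, `GEBV(%)` = gebv$gebv,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convergence diagnostics: split-chain PSRF and effective sample size
#'
#' Potential scale reduction factor (split-chain Gelman-Rubin R-hat) and a
#' crude effective sample size (retained draws divided by the summed
#' autocorrelation, truncated at the first negative value) per reported
#' parameter. With a single chain the split halves still give a
#' within-chain PSRF, with a warning.
#'
#' @param summary a `posterior_summary`.
#' @param parameters columns to diagnose (default: all with positive
#'   variance).
#' @return data.frame `parameter`, `psrf`, `ess`.
#' @export
convergence_diagnostics <- function(summary, parameters = NULL) {
  stopifnot(inherits(summary, "posterior_summary"))
  if (length(summary$chains) < 2L)
    warning("single chain: PSRF computed from split halves only")
  if (is.null(parameters)) {
    sds <- apply(do.call(rbind, summary$chains), 2L, sd)
    parameters <- names(sds)[sds > 0]
  }
  out <- lapply(parameters, function(p) {
    dm <- sapply(summary$chains, function(d) d[, p])
    dm <- as.matrix(dm)
    data.frame(parameter = p, psrf = split_rhat(dm),
               ess = ess_acf(dm), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# split-chain Gelman-Rubin statistic on a draws x chains matrix
split_rhat <- function(dm) {
  n <- nrow(dm)
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  splits <- do.call(cbind, lapply(seq_len(ncol(dm)), function(j)
    cbind(dm[seq_len(half), j], dm[(n - half + 1L):n, j])))
  m <- ncol(splits); nn <- nrow(splits)
  mu_j <- colMeans(splits)
  s2_j <- apply(splits, 2L, var)
  W <- mean(s2_j)
  B <- nn * var(mu_j)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size via initial-positive-sequence autocorrelation
ess_acf <- function(dm) {
  total <- 0
  for (j in seq_len(ncol(dm))) {
    x <- dm[, j]
    if (sd(x) == 0) { total <- total + length(x); next }
    rho <- drop(acf(x, lag.max = min(100L, length(x) - 1L),
                    plot = FALSE)$acf)[-1]
    neg <- which(rho < 0)
    if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
    total <- total + length(x) / (1 + 2 * sum(rho))
  }
  total
}
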