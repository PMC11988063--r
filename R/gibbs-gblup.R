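#' Gibbs sampler for the random-regression GBLUP model
#'
#' Stage-2 inference on adjusted test-day records `y* = Z1 a + Z2 p + Z3 h
#' + e` where the additive genetic (`a`), permanent environmental (`p`) and
#' herd (`h`) effects are coefficients of normalized Legendre polynomials
#' of days in milk, with covariance structures `G (x) Ka`, `I (x) Kp` and
#' `I (x) Kh` (`(x)` the Kronecker product, `G` the genomic relationship
#' matrix). Residual variances are homogeneous within and heterogeneous
#' between lactation-period (days-in-milk) classes. An overall mean with a
#' flat prior is always included.
#'
#' Block Gibbs updates: the full coefficient blocks from their multivariate
#' normal full conditionals, `Ka`/`Kp`/`Kh` from inverse-Wishart (scaled
#' inverse-chi-square when the order is 0) and each residual-class variance
#' from a scaled inverse-chi-square. When the model reduces to order-0
#' additive-plus-residual with a balanced class layout, updates run in the
#' eigenbasis of `G`, where every full conditional is diagonal.
#'
#' Reported per draw, on the phenotypic scale: `Va` (the genetic variance
#' of the trajectory averaged over the days-in-milk window), `Vpe`,
#' `Vherd`, `Ve` (record-weighted mean residual variance) and
#' `h2 = Va / (Va + Ve)`.
#'
#' @param y adjusted record vector (fat %).
#' @param days_in_milk per-record days in milk.
#' @param animal_id per-record animal identifier; all must index `G`.
#' @param G a `grm` from [vanraden_grm()] (stabilize with
#'   [stabilize_grm()]) or a positive-definite matrix with animal-id
#'   dimnames.
#' @param order Legendre polynomial order m (default 0).
#' @param config an [mcmc_config()].
#' @param herd_id per-record herd identifier (required when
#'   `include_herd = TRUE`).
#' @param include_pe,include_herd include the permanent-environment / herd
#'   random-regression terms.
#' @param residual_class_breaks upper DIM bounds separating the residual
#'   classes (default bands 8-45, 46-115, 116-225, 226-340); `NULL` for a
#'   single homogeneous class.
#' @param dim_window closed DIM window.
#' @param priors optional list overriding `nu_scalar` (4), `s2_a0`,
#'   `s2_e0` (auto-scaled from `var(y)`), `nu_K`, `S_K`, and `fixed` (a
#'   list of known `Ka`, `Kp`, `Kh`, `R` values that are then not updated;
#'   used for conjugate closed-form checks).
#' @return object of class `posterior_summary`.
#' @seealso [bayesr_snp_engine()], [gebv_from_posterior()],
#'   [convergence_diagnostics()]
#' @export
gibbs_rr_gblup <- function(y, days_in_milk, animal_id, G,
                           order = 0L, config = mcmc_config(),
                           herd_id = NULL,
                           include_pe = FALSE, include_herd = FALSE,
                           residual_class_breaks = c(45, 115, 225),
                           dim_window = c(8, 340),
                           priors = list()) {
  stopifnot(inherits(config, "mcmc_config"))
  N <- length(y)
  stopifnot(length(days_in_milk) == N, length(animal_id) == N)
  if (include_herd && is.null(herd_id))
    stop("include_herd = TRUE requires herd_id", call. = FALSE)
  ids <- sort(unique(as.character(animal_id)))
  n <- length(ids)
  ia <- match(as.character(animal_id), ids)
  Gm <- if (inherits(G, "grm")) G$values else G
  if (!all(ids %in% rownames(Gm)))
    stop("G lacks rows for some animals with records", call. = FALSE)
  Gm <- Gm[ids, ids]
  q <- order + 1L
  phi <- legendre_covariates(days_in_milk, order, dim_window)

  if (is.null(residual_class_breaks)) {
    cls <- rep(1L, N)
  } else {
    cls <- findInterval(days_in_milk, residual_class_breaks,
                        left.open = TRUE) + 1L
  }
  cls <- match(cls, sort(unique(cls)))  # drop empty classes
  n_cls <- max(cls)
  nc <- tabulate(cls, n_cls)

  vy <- max(var(y), 1e-12)  # guard degenerate constant input
  pr <- list(nu_scalar = 4, s2_a0 = 0.05 * vy, s2_e0 = 0.5 * vy,
             nu_K = q + 2, S_K = diag(0.01, q), fixed = NULL)
  pr[names(priors)] <- priors
  fixed <- pr$fixed

  # grid for phenotype-scale variance of the genetic trajectory
  Pg <- legendre_covariates(seq(dim_window[1], dim_window[2]), order,
                            dim_window)
  scale_K <- function(K) mean(rowSums((Pg %*% K) * Pg))

  # fast path: order-0 additive + residual with identical per-animal class
  # layout -> all full conditionals diagonal in the eigenbasis of G
  counts <- matrix(0L, n, n_cls)
  counts[cbind(ia, cls)] <- 0L  # init shape
  for (c_ in seq_len(n_cls))
    counts[, c_] <- tabulate(ia[cls == c_], n)
  balanced <- all(apply(counts, 2L, function(col) length(unique(col)) == 1L))
  fast <- (order == 0L) && !include_pe && !include_herd && balanced

  ev <- eigen(Gm, symmetric = TRUE)
  if (min(ev$values) <= 1e-10)
    stop("G is not positive definite; apply stabilize_grm() first",
         call. = FALSE)
  Ginv <- ev$vectors %*% (t(ev$vectors) / ev$values)

  if (!fast) {
    Z1 <- sparseMatrix(i = rep(seq_len(N), q),
                       j = rep((ia - 1L) * q, q) + rep(seq_len(q), each = N),
                       x = as.vector(phi), dims = c(N, n * q))
    if (include_herd) {
      herd_lev <- sort(unique(as.character(herd_id)))
      ih <- match(as.character(herd_id), herd_lev)
      nh <- length(herd_lev)
      Zh <- sparseMatrix(i = rep(seq_len(N), q),
                         j = rep((ih - 1L) * q, q) + rep(seq_len(q), each = N),
                         x = as.vector(phi), dims = c(N, nh * q))
    }
  }

  n_keep <- n_retained_draws(config)
  par_names <- c("mu", "Va", "Vpe", "Vherd", "Ve", "h2")
  chains <- vector("list", config$n_chains)
  coef_sum <- matrix(0, n, q)
  seeds <- chain_seeds(config)

  for (ch in seq_len(config$n_chains)) {
    set.seed(seeds[ch])
    mu <- mean(y)
    Ka <- if (!is.null(fixed$Ka)) as.matrix(fixed$Ka) else diag(0.3 * vy, q)
    Kp <- if (!is.null(fixed$Kp)) as.matrix(fixed$Kp) else diag(0.1 * vy, q)
    Kh <- if (!is.null(fixed$Kh)) as.matrix(fixed$Kh) else diag(0.1 * vy, q)
    s2e <- if (!is.null(fixed$R)) rep_len(fixed$R, n_cls)
           else rep(0.5 * vy, n_cls)
    alpha <- numeric(n * q)
    pcoef <- if (include_pe) matrix(0, n, q)
    hcoef <- if (include_herd) matrix(0, nh, q)
    draws <- matrix(NA_real_, n_keep, length(par_names),
                    dimnames = list(NULL, par_names))
    kept <- 0L

    for (it in seq_len(config$n_iter)) {
      w_r <- 1 / s2e[cls]                     # per-record precisions

      if (fast) {
        # ---- eigenbasis updates (diagonal full conditionals) ----
        phi0 <- phi[1, 1]                     # 1/sqrt(2), constant
        wa <- sum(counts[1, ] / s2e)          # identical for every animal
        r <- y - mu
        s <- rowsum(r * w_r, ia)[, 1] * phi0
        st <- drop(crossprod(ev$vectors, s))
        d <- phi0^2 * wa + 1 / (Ka[1, 1] * ev$values)
        at <- st / d + rnorm(n) / sqrt(d)
        alpha <- drop(ev$vectors %*% at)
        g_rec <- phi0 * alpha[ia]
        if (is.null(fixed$Ka)) {
          ss_a <- sum(at^2 / ev$values)
          Ka[1, 1] <- rinvchisq_post(pr$nu_scalar, pr$s2_a0, ss_a, n)
        }
        e <- y - mu - g_rec
        prec_mu <- sum(w_r)
        mu <- sum((y - g_rec) * w_r) / prec_mu + rnorm(1) / sqrt(prec_mu)
        e <- y - mu - g_rec
        if (is.null(fixed$R)) {
          for (c_ in seq_len(n_cls))
            s2e[c_] <- rinvchisq_post(pr$nu_scalar, pr$s2_e0,
                                      sum(e[cls == c_]^2), nc[c_])
        }
      } else {
        # ---- general block updates ----
        part <- mu +
          (if (include_pe) rowSums(phi * pcoef[ia, , drop = FALSE]) else 0) +
          (if (include_herd) rowSums(phi * hcoef[ih, , drop = FALSE]) else 0)
        r <- y - part
        C <- as.matrix(crossprod(Z1, Z1 * w_r)) + kronecker(Ginv, solve(Ka))
        rhs <- drop(crossprod(Z1, r * w_r))
        L <- chol(C)
        m_a <- backsolve(L, forwardsolve(t(L), rhs))
        alpha <- m_a + backsolve(L, rnorm(n * q))
        A <- matrix(alpha, nrow = n, byrow = TRUE)
        g_rec <- rowSums(phi * A[ia, , drop = FALSE])
        if (is.null(fixed$Ka))
          Ka <- rinvwishart(pr$nu_K + n, pr$S_K + crossprod(A, Ginv %*% A))

        if (include_pe) {
          r <- y - mu - g_rec -
            (if (include_herd) rowSums(phi * hcoef[ih, , drop = FALSE]) else 0)
          Kpinv <- solve(Kp)
          for (i in seq_len(n)) {
            rows <- which(ia == i)
            Pi <- phi[rows, , drop = FALSE]
            Ci <- crossprod(Pi, Pi * w_r[rows]) + Kpinv
            Li <- chol(Ci)
            mi <- backsolve(Li, forwardsolve(t(Li),
                                             crossprod(Pi, r[rows] * w_r[rows])))
            pcoef[i, ] <- mi + backsolve(Li, rnorm(q))
          }
          if (is.null(fixed$Kp))
            Kp <- rinvwishart(pr$nu_K + n, pr$S_K + crossprod(pcoef))
        }
        if (include_herd) {
          r <- y - mu - g_rec -
            (if (include_pe) rowSums(phi * pcoef[ia, , drop = FALSE]) else 0)
          Khinv <- solve(Kh)
          for (i in seq_len(nh)) {
            rows <- which(ih == i)
            Pi <- phi[rows, , drop = FALSE]
            Ci <- crossprod(Pi, Pi * w_r[rows]) + Khinv
            Li <- chol(Ci)
            mi <- backsolve(Li, forwardsolve(t(Li),
                                             crossprod(Pi, r[rows] * w_r[rows])))
            hcoef[i, ] <- mi + backsolve(Li, rnorm(q))
          }
          if (is.null(fixed$Kh))
            Kh <- rinvwishart(pr$nu_K + nh, pr$S_K + crossprod(hcoef))
        }
        fit_re <- g_rec +
          (if (include_pe) rowSums(phi * pcoef[ia, , drop = FALSE]) else 0) +
          (if (include_herd) rowSums(phi * hcoef[ih, , drop = FALSE]) else 0)
        prec_mu <- sum(w_r)
        mu <- sum((y - fit_re) * w_r) / prec_mu + rnorm(1) / sqrt(prec_mu)
        e <- y - mu - fit_re
        if (is.null(fixed$R)) {
          for (c_ in seq_len(n_cls))
            s2e[c_] <- rinvchisq_post(pr$nu_scalar, pr$s2_e0,
                                      sum(e[cls == c_]^2), nc[c_])
        }
      }

      if (it > config$burn_in &&
          (it - config$burn_in) %% config$thin == 0L) {
        kept <- kept + 1L
        Va <- if (fast) Ka[1, 1] / 2 else scale_K(Ka)
        Vpe <- if (include_pe) scale_K(Kp) else 0
        Vhe <- if (include_herd) scale_K(Kh) else 0
        Ve <- sum(nc * s2e) / N
        draws[kept, ] <- c(mu, Va, Vpe, Vhe, Ve, Va / (Va + Ve))
        coef_sum <- coef_sum +
          (if (fast) cbind(alpha) else matrix(alpha, nrow = n, byrow = TRUE))
      }
    }
    chains[[ch]] <- draws
  }

  coef_mean <- coef_sum / (config$n_chains * n_keep)
  rownames(coef_mean) <- ids
  colnames(coef_mean) <- paste0("a", seq(0, order))
  new_posterior_summary(engine = "rr_gblup", chains = chains,
                        coef_mean = coef_mean, animal_ids = ids,
                        order = order, dim_window = dim_window,
                        config = config,
                        extra = list(fast_path = fast, n_records = N,
                                     n_residual_classes = n_cls))
}
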