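test_that("normalized Legendre covariates match closed forms", {
  # order 0: constant 1/sqrt(2)
  phi0 <- legendre_covariates(c(8, 100, 340), 0)
  expect_equal(unname(phi0[, 1]), rep(sqrt(1 / 2), 3))
  # window midpoint maps to x = 0 where odd polynomials vanish
  phi1 <- legendre_covariates(174, 1)
  expect_equal(unname(phi1[1, 2]), 0)
  # x = 1: phi_2 = sqrt(5/2) * P_2(1) = sqrt(5/2)
  phi2 <- legendre_covariates(340, 2)
  expect_equal(unname(phi2[1, 3]), sqrt(5 / 2))
  # recurrence spot check at x = 0.5: P_3(0.5) = -7/16
  t_half <- 8 + 0.75 * (340 - 8)
  phi3 <- legendre_covariates(t_half, 3)
  expect_equal(unname(phi3[1, 4]), sqrt(7 / 2) * (-7 / 16), tolerance = 1e-12)
  expect_error(legendre_covariates(5, 1), "window")
})

test_that("retained draw counts follow the thinning arithmetic", {
  cfg <- mcmc_config(n_chains = 2, n_iter = 25000, burn_in = 5000,
                     thin = 10)
  expect_equal(n_retained_draws(cfg), 2000)
  expect_error(mcmc_config(n_iter = 100, burn_in = 100), "burn_in")
  gm <- toy_genotypes(8, 60, seed = 1)
  G <- stabilize_grm(vanraden_grm(gm))
  set.seed(3)
  y <- rnorm(16)
  post <- gibbs_rr_gblup(y, rep(c(50, 200), 8),
                         rep(rownames(gm$calls), each = 2), G,
                         config = mcmc_config(2, 230, 30, 7, seed = 4))
  expect_equal(post$n_draws_per_chain, (230 - 30) %/% 7)
  expect_equal(nrow(post$chains[[1]]), 28)
})

test_that("with fixed variances the sampler reduces to the BLUP solution", {
  # small instance solvable densely; both the balanced fast path and the
  # general path must agree with the closed form
  cfg <- sim_config(n_snps = 300, seed = 55, fixed_effect_sd = 0)
  pop <- simulate_population(cfg, n_animals = 40)
  rec <- pop$records
  G <- stabilize_grm(vanraden_grm(pop$genotypes))
  ids <- sort(unique(rec$animal_id))
  Ka <- 0.024; s2e <- 0.106
  blup_oracle <- function(rec) {
    phi0 <- 1 / sqrt(2)
    Z <- outer(rec$animal_id, ids, "==") * phi0
    X <- matrix(1, nrow(rec), 1)
    W <- cbind(X, Z)
    C <- crossprod(W) / s2e
    Gi <- solve(G$values[ids, ids]) / Ka
    C[-1, -1] <- C[-1, -1] + Gi
    drop(solve(C, crossprod(W, rec$fat_pct) / s2e))
  }
  run <- function(rec) {
    gibbs_rr_gblup(rec$fat_pct, rec$days_in_milk, rec$animal_id, G,
                   config = mcmc_config(2, 6000, 500, 1, seed = 2),
                   residual_class_breaks = NULL,
                   priors = list(fixed = list(Ka = Ka, R = s2e)))
  }
  post <- run(rec)
  expect_true(post$fast_path)
  sol <- blup_oracle(rec)
  mu_hat <- mean(sapply(post$chains, function(d) mean(d[, "mu"])))
  expect_lt(abs(mu_hat - sol[1]), 0.02)
  expect_lt(max(abs(post$coef_mean[, 1] - sol[-1])), 0.02)
  # drop one record: unbalanced design forces the general path
  rec_u <- rec[-1, ]
  post_u <- run(rec_u)
  expect_false(post_u$fast_path)
  sol_u <- blup_oracle(rec_u)
  expect_lt(max(abs(post_u$coef_mean[, 1] - sol_u[-1])), 0.02)
})

test_that("GEBVs are invariant to shifting all adjusted records", {
  gm <- toy_genotypes(10, 80, seed = 6)
  G <- stabilize_grm(vanraden_grm(gm))
  set.seed(9)
  rec_ids <- rep(rownames(gm$calls), each = 4)
  dims <- rep(c(30, 120, 210, 300), 10)
  y <- rnorm(40)
  cfgm <- mcmc_config(1, 400, 100, 3, seed = 8)
  p1 <- gibbs_rr_gblup(y, dims, rec_ids, G, config = cfgm)
  p2 <- gibbs_rr_gblup(y + 5, dims, rec_ids, G, config = cfgm)
  expect_equal(gebv_from_posterior(p1)$gebv, gebv_from_posterior(p2)$gebv,
               tolerance = 1e-12)
})

test_that("null response concentrates variance components near zero", {
  gm <- toy_genotypes(12, 60, seed = 2)
  G <- stabilize_grm(vanraden_grm(gm))
  y0 <- rep(0, 48)
  post <- gibbs_rr_gblup(y0, rep(c(40, 140, 240, 320), 12),
                         rep(rownames(gm$calls), each = 4), G,
                         config = mcmc_config(1, 600, 200, 2, seed = 3))
  expect_lt(post$means["Va"], 1e-6)
  expect_lt(post$means["Ve"], 1e-6)
})

test_that("heritability arithmetic", {
  expect_equal(round(heritability(0.012, 0.106), 2), 0.10)
  expect_equal(heritability(0, 1), 0)
  expect_equal(heritability(1, 0), 1)
  expect_error(heritability(0, 0), "undefined")
  expect_error(heritability(-0.1, 1), "non-negative")
  # vectorized over draws
  expect_equal(heritability(c(1, 1), c(3, 1)), c(0.25, 0.5))
})

test_that("the random-regression path recovers a DIM-varying trajectory", {
  # order-1 fit on data whose genetic effect varies linearly in DIM
  cfg <- sim_config(n_snps = 200, seed = 61, fixed_effect_sd = 0,
                    legendre_order = 1, records_per_lactation = 6)
  pop <- simulate_population(cfg, n_animals = 60)
  G <- stabilize_grm(vanraden_grm(pop$genotypes))
  post <- gibbs_rr_gblup(pop$records$fat_pct, pop$records$days_in_milk,
                         pop$records$animal_id, G, order = 1,
                         config = mcmc_config(1, 600, 200, 4, seed = 7),
                         residual_class_breaks = NULL)
  expect_false(post$fast_path)
  expect_equal(dim(post$coef_mean), c(60, 2))
  g <- gebv_from_posterior(post)
  bv <- pop$truth$true_breeding_values[g$animal_id]
  expect_gt(cor(g$gebv, bv), 0.3)
})

test_that("split-chain PSRF separates mixed from unmixed chains", {
  fake_summary <- function(chains) {
    structure(list(engine = "rr_gblup", chains = chains,
                   n_draws_per_chain = nrow(chains[[1]])),
              class = "posterior_summary")
  }
  set.seed(5)
  stat <- matrix(rnorm(400), dimnames = list(NULL, "h2"))
  # identical stationary chains: PSRF at 1 within split noise
  s_same <- fake_summary(list(stat, stat, stat))
  d_same <- convergence_diagnostics(s_same, "h2")
  expect_lt(abs(d_same$psrf - 1), 0.05)
  # disjoint constant-level chains: PSRF far above 1
  s_bad <- fake_summary(list(stat, stat + 50))
  d_bad <- convergence_diagnostics(s_bad, "h2")
  expect_gt(d_bad$psrf, 5)
  # a well-mixed conjugate run diagnoses as converged
  gm <- toy_genotypes(8, 40, seed = 4)
  G <- stabilize_grm(vanraden_grm(gm))
  set.seed(11)
  y <- rnorm(24)
  post <- gibbs_rr_gblup(y, rep(c(60, 170, 280), 8),
                         rep(rownames(gm$calls), each = 3), G,
                         config = mcmc_config(3, 1500, 300, 2, seed = 12),
                         residual_class_breaks = NULL)
  dd <- convergence_diagnostics(post, c("Ve", "h2"))
  expect_true(all(dd$psrf < 1.1))
  expect_true(all(dd$ess > 50))
  # single chain falls back to split halves with a warning
  expect_warning(convergence_diagnostics(fake_summary(list(stat)), "h2"),
                 "single chain")
})

test_that("posterior-mean h2 covers the simulated truth over replicates", {
  # direct simulate-and-fit replicates at reduced size; the 90% credible
  # interval should cover h2 = 0.102 in most replicates
  n_rep <- 6
  cover <- logical(n_rep)
  h2_hat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_snps = 800, seed = 100 + r, fixed_effect_sd = 0)
    pop <- simulate_population(cfg, n_animals = 150)
    G <- stabilize_grm(vanraden_grm(pop$genotypes))
    post <- gibbs_rr_gblup(pop$records$fat_pct, pop$records$days_in_milk,
                           pop$records$animal_id, G,
                           config = mcmc_config(1, 1200, 300, 3,
                                                seed = 100 + r))
    dr <- posterior_draws(post, "h2")
    ci <- quantile(dr, c(0.05, 0.95))
    truth <- heritability(0.012, 0.106)
    cover[r] <- ci[1] <= truth && truth <= ci[2]
    h2_hat[r] <- mean(dr)
  }
  expect_gte(sum(cover), ceiling(0.8 * n_rep) - 1)
  expect_equal(mean(h2_hat), heritability(0.012, 0.106), tolerance = 0.35)
})
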