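test_that("design matrices encode the stage-1 model", {
  rec <- toy_records(n_cows = 2, n_rec = 4)
  rec$lactation_number <- rep(c(1L, 2L), each = 4)
  d <- build_design(rec)
  # 2 lactations x 1 CDC x 1 year-month: intercept + one contrast
  expect_equal(ncol(d$X), 2)
  # single level everywhere: intercept only
  d1 <- build_design(toy_records(n_cows = 2, n_rec = 4))
  expect_equal(ncol(d1$X), 1)
  # incidence contract
  expect_true(all(Matrix::rowSums(d$Z1) == 1))
  expect_true(all(Matrix::rowSums(d$Z2) == 1))
  expect_error(build_design(rec[, -1]), "required columns")
  rec$cdc_id[3] <- NA
  expect_error(build_design(rec), "missing factor levels")
})

test_that("EM-REML matches closed-form ANOVA REML on a balanced layout", {
  # balanced one-way: n animals x k records, no herd or fixed structure
  set.seed(42)
  n <- 40; k <- 6
  a <- rnorm(n, 0, sqrt(0.4))
  y <- 4 + rep(a, each = k) + rnorm(n * k, 0, sqrt(1.2))
  rec <- data.frame(animal_id = rep(sprintf("A%02d", 1:n), each = k),
                    herd_id = "H1", cdc_id = "C1", lactation_number = 1L,
                    days_in_milk = rep(seq(20, 320, length.out = k), n),
                    year_month = "YM1", fat_pct = y)
  d <- build_design(rec)
  # the single shared herd level is confounded with the intercept, so its
  # variance is pinned to make the layout a clean one-way design
  est <- estimate_variances_em_reml(d, fix = list(sigma2_h = 1e-12),
                                    tolerance = 1e-9, max_iter = 5000)
  # oracle: balanced one-way ANOVA estimators (equal to REML here)
  ybar_i <- tapply(y, rec$animal_id, mean)
  msb <- k * var(ybar_i)
  msw <- sum((y - rep(ybar_i[unique(rec$animal_id)], each = k))^2) /
    (n * (k - 1))
  expect_equal(est$sigma2_e, msw, tolerance = 1e-5)
  expect_equal(est$sigma2_a, (msb - msw) / k, tolerance = 1e-4)
})

test_that("EM-REML agrees with an independent REML fit", {
  skip_if_not_installed("lme4")
  # multi-cow herds so animal and herd variance are well identified
  # (in mostly-single-cow herds the two are confounded and any REML
  # optimizer sits on a ridge)
  set.seed(15)
  n_herds <- 30; cows_per_herd <- 5; k <- 4
  n <- n_herds * cows_per_herd
  herd_of <- rep(sprintf("H%02d", seq_len(n_herds)), each = cows_per_herd)
  a <- rnorm(n, 0, sqrt(0.3))
  h <- rnorm(n_herds, 0, sqrt(0.2))
  y <- 4 + rep(a, each = k) + rep(h[as.integer(factor(herd_of))], each = k) +
    rnorm(n * k, 0, 1)
  rec <- data.frame(animal_id = rep(sprintf("A%03d", seq_len(n)), each = k),
                    herd_id = rep(herd_of, each = k),
                    cdc_id = "C1", lactation_number = 1L,
                    days_in_milk = rep(seq(20, 320, length.out = k), n),
                    year_month = "YM1", fat_pct = y)
  d <- build_design(rec)
  est <- estimate_variances_em_reml(d, tolerance = 1e-9, max_iter = 10000)
  lf <- lme4::lmer(fat_pct ~ 1 + (1 | animal_id) + (1 | herd_id),
                   data = rec, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  ref <- setNames(vc$vcov, vc$grp)
  expect_equal(est$sigma2_a, unname(ref["animal_id"]), tolerance = 1e-3)
  expect_equal(est$sigma2_h, unname(ref["herd_id"]), tolerance = 1e-3)
  expect_equal(est$sigma2_e, unname(ref["Residual"]), tolerance = 1e-3)
})

test_that("EM-REML recovers simulated variance components", {
  cfg <- sim_config(n_snps = 200, seed = 77, fixed_effect_sd = 0)
  pop <- simulate_population(cfg, n_animals = 400)
  d <- build_design(pop$records)
  est <- estimate_variances_em_reml(d, max_iter = 5000)
  expect_equal(est$sigma2_a + est$sigma2_h, 0.012, tolerance = 0.20)
  expect_equal(est$sigma2_e, 0.106, tolerance = 0.20)
  # pure noise: the animal component collapses to the boundary
  recn <- pop$records
  set.seed(1)
  recn$fat_pct <- rnorm(nrow(recn))
  dn <- build_design(recn)
  estn <- estimate_variances_em_reml(dn, tolerance = 5e-6,
                                     max_iter = 5000)
  expect_lt(estn$sigma2_a, 0.02)
})

test_that("MME solutions equal a dense generalized-least-squares oracle", {
  rec <- toy_records(n_cows = 2, n_rec = 2, seed = 2)
  rec$herd_id <- c("H1", "H1", "H2", "H2")
  d <- build_design(rec)
  vc <- list(sigma2_a = 0.5, sigma2_h = 0.25, sigma2_e = 1)
  fit <- solve_mme(d, vc)
  # oracle: assemble Henderson's equations explicitly and solve densely
  X <- d$X; Z1 <- as.matrix(d$Z1); Z2 <- as.matrix(d$Z2)
  W <- cbind(X, Z1, Z2)
  C <- crossprod(W)
  idx_a <- ncol(X) + seq_len(ncol(Z1))
  idx_h <- ncol(X) + ncol(Z1) + seq_len(ncol(Z2))
  diag(C)[idx_a] <- diag(C)[idx_a] + 1 / 0.5
  diag(C)[idx_h] <- diag(C)[idx_h] + 1 / 0.25
  sol <- solve(C, crossprod(W, rec$fat_pct))
  expect_equal(unname(fit$b_hat), sol[seq_len(ncol(X))], tolerance = 1e-10)
  expect_equal(unname(fit$a_hat), sol[idx_a], tolerance = 1e-10)
  expect_equal(unname(fit$h_hat), sol[idx_h], tolerance = 1e-10)
  # reconstruction identity
  expect_equal(unname(drop(X %*% fit$b_hat) + drop(Z1 %*% fit$a_hat) +
                        drop(Z2 %*% fit$h_hat)) + fit$e_hat,
               rec$fat_pct, tolerance = 1e-8)
})

test_that("infinite shrinkage drives animal BLUPs to zero", {
  rec <- toy_records(n_cows = 4, n_rec = 4, seed = 6)
  d <- build_design(rec)
  fit <- solve_mme(d, list(sigma2_a = 1e-10, sigma2_h = 1e-10,
                           sigma2_e = 1))
  expect_true(all(abs(fit$a_hat) < 1e-6))
})

test_that("adjusted records decompose additively", {
  rec <- toy_records(n_cows = 5, n_rec = 4, seed = 10)
  d <- build_design(rec)
  fit <- solve_mme(d, list(sigma2_a = 0.1, sigma2_h = 0.05, sigma2_e = 0.3))
  adj <- adjust_records(fit)
  # exact additivity and equality with y - X b_hat
  expect_equal(adj$afp, adj$ife + adj$are + adj$hre)
  expect_equal(adj$afp, unname(rec$fat_pct - drop(d$X %*% fit$b_hat)),
               tolerance = 1e-10)
  # location invariance: shifting every record leaves afp unchanged
  rec2 <- rec; rec2$fat_pct <- rec2$fat_pct + 1
  d2 <- build_design(rec2)
  fit2 <- solve_mme(d2, list(sigma2_a = 0.1, sigma2_h = 0.05,
                             sigma2_e = 0.3))
  expect_equal(adjust_records(fit2)$afp, adj$afp, tolerance = 1e-8)
})

test_that("worked-example component table composes exactly", {
  tab <- read.csv(extdata("example_adjusted_records.csv"))
  out <- compose_adjusted_records(tab)
  expect_equal(out$afp[6], 0.79)
  expect_equal(max(out$afp), 0.87)
  expect_equal(out$afp[8], -0.84)
  # printed AFP differs from the exact sum only by print rounding
  expect_true(all(abs(out$afp - tab$afp_printed) <= 0.01 + 1e-12))
})

test_that("animal-effect accuracy grows with records per animal", {
  score <- function(k, seed) {
    cfg <- sim_config(n_snps = 60, seed = seed, fixed_effect_sd = 0,
                      records_per_lactation = k)
    pop <- simulate_population(cfg, n_animals = 80)
    d <- build_design(pop$records)
    fit <- solve_mme(d, list(sigma2_a = 0.012, sigma2_h = 1e-8,
                             sigma2_e = 0.106))
    cor(fit$a_hat[names(pop$truth$true_breeding_values)],
        pop$truth$true_breeding_values)
  }
  seeds <- 1:10
  r2_few <- vapply(seeds, function(s) score(2L, s), numeric(1))
  r2_many <- vapply(seeds, function(s) score(10L, s), numeric(1))
  expect_gt(mean(r2_many), mean(r2_few))
})
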