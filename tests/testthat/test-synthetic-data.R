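test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(herd_size_distribution = c(0.5, 0.4)),
               "sum to 1")
  expect_error(sim_config(mixture_proportions = c(0.5, 0.5, 0, 0.1)),
               "sum to 1")
  expect_error(sim_config(mixture_variance_scales = c(0.1, 1e-4, 1e-3, 1e-2)),
               "class-1")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(variance_components =
                            list(Va = -1, Vpe = 0, Vherd = 0, Ve = 1)),
               ">= 0")
})

test_that("herd sizes follow the configured distribution", {
  cfg <- sim_config(n_herds = 10000, seed = 42)
  herds <- simulate_herds(cfg)
  sizes <- table(herds$herd_id)
  # single-cow-herd share matches the configured two-thirds within 0.02
  expect_equal(mean(sizes == 1), 839 / 1260, tolerance = 0.02 / (839 / 1260))
  # conservation: herd sizes sum to the animal count
  expect_equal(sum(sizes), nrow(herds))
  expect_equal(length(unique(herds$animal_id)), nrow(herds))
})

test_that("degenerate herd distribution and determinism", {
  cfg <- sim_config(n_herds = 50,
                    herd_size_distribution = 1, seed = 7)
  herds <- simulate_herds(cfg)
  expect_equal(length(unique(herds$herd_id)), 50)
  expect_equal(nrow(herds), 50)
  expect_identical(herds, simulate_herds(cfg))
  # exact animal-count targeting
  h2 <- simulate_herds(sim_config(seed = 3), n_animals = 123)
  expect_equal(nrow(h2), 123)
})

test_that("genotypes are Hardy-Weinberg draws from the configured MAF range", {
  cfg <- sim_config(n_snps = 300, maf_range = c(0.5, 0.5), seed = 5)
  gm <- simulate_genotypes(cfg, 400)
  expect_true(all(abs(colMeans(gm$calls) - 1) < 4 * sqrt(0.5 / 400) + 1e-9))
  # bit-exact reproducibility
  gm2 <- simulate_genotypes(cfg, 400)
  expect_identical(gm$calls, gm2$calls)
  # observed MAF within 3 binomial SEs of the drawn frequency
  cfg3 <- sim_config(n_snps = 400, seed = 11)
  gm3 <- simulate_genotypes(cfg3, 2000)
  p <- attr(gm3, "true_freq")
  se <- sqrt(p * (1 - p) / (2 * 2000))
  frac_ok <- mean(abs(allele_freq(gm3) - p) <= 3 * se)
  expect_gte(frac_ok, 0.99)
})

test_that("SNP effects follow the four-component mixture", {
  gm <- simulate_genotypes(sim_config(n_snps = 10000, seed = 2), 40)
  # null model: all effects exactly zero
  cfg0 <- sim_config(n_snps = 10000,
                     mixture_proportions = c(1, 0, 0, 0), seed = 2)
  tr0 <- simulate_snp_effects(cfg0, gm)
  expect_true(all(tr0$true_snp_effects == 0))
  expect_true(all(tr0$true_breeding_values == 0))
  # single non-null class: empirical effect variance matches its scale
  cfg4 <- sim_config(n_snps = 10000,
                     mixture_proportions = c(0, 0, 0, 1),
                     exact_bv_scale = FALSE, seed = 2)
  tr4 <- simulate_snp_effects(cfg4, gm)
  p <- allele_freq(gm)
  expected_var <- 1e-2 * 0.012 / (1e-2 * sum(2 * p * (1 - p)))
  expect_equal(var(tr4$true_snp_effects), expected_var, tolerance = 0.05)
  # class counts are multinomial draws from the proportions
  cfg <- sim_config(n_snps = 10000, seed = 8)
  tr <- simulate_snp_effects(cfg, gm)
  counts <- tabulate(tr$true_component_assignments, 4)
  gof <- suppressWarnings(
    stats::chisq.test(counts, p = cfg$mixture_proportions))
  expect_gt(gof$p.value, 0.001)
})

test_that("true breeding values equal centered genotypes times effects", {
  cfg <- sim_config(n_snps = 500, seed = 13)
  gm <- simulate_genotypes(cfg, 50)
  tr <- simulate_snp_effects(cfg, gm)
  W <- sweep(gm$calls, 2, 2 * allele_freq(gm))
  expect_equal(unname(tr$true_breeding_values),
               unname(drop(W %*% tr$true_snp_effects)))
  # exact calibration: realized breeding-value variance equals Va
  expect_equal(var(tr$true_breeding_values), 0.012, tolerance = 1e-12)
})

test_that("phenotypes have the configured structure and variances", {
  # degenerate case: all variances and fixed effects zero -> records
  # constant at the population mean
  cfg0 <- sim_config(n_snps = 50, fixed_effect_sd = 0,
                     variance_components = list(Va = 0, Vpe = 0,
                                                Vherd = 0, Ve = 0),
                     seed = 4)
  pop0 <- simulate_population(cfg0, n_animals = 20)
  expect_true(all(pop0$records$fat_pct == 4))
  # structural contract: records per lactation, DIM window
  cfg <- sim_config(n_snps = 50, records_per_lactation = 6,
                    n_lactations = 2, seed = 4)
  pop <- simulate_population(cfg, n_animals = 30)
  counts <- table(pop$records$animal_id, pop$records$lactation_number)
  expect_true(all(counts == 6))
  expect_true(all(pop$records$days_in_milk >= 8 &
                    pop$records$days_in_milk <= 340))
  # variance decomposition of per-animal means: Va + Ve / k
  cfgv <- sim_config(n_snps = 400, fixed_effect_sd = 0, seed = 17)
  popv <- simulate_population(cfgv, n_animals = 1500)
  m <- tapply(popv$records$fat_pct, popv$records$animal_id, mean)
  expect_equal(var(m), 0.012 + 0.106 / 8, tolerance = 0.15)
})

test_that("defect injection returns an exact manifest", {
  cfg <- sim_config(n_snps = 60, seed = 9)
  pop <- simulate_population(cfg, n_animals = 40)
  # empty spec is the identity
  clean <- inject_defects(pop$records, pop$genotypes, defect_spec())
  expect_identical(clean$records, pop$records)
  expect_identical(clean$genotypes$calls, pop$genotypes$calls)
  expect_length(clean$manifest, 0)
  # injected defects are where the manifest says
  spec <- defect_spec(duplicate_animals = 1, low_call_animals = 2,
                      low_call_snps = 2, monomorphic_snps = 1,
                      nonautosomal_snps = 3, outlier_cows = 1,
                      short_lactation_cows = 1)
  bad <- inject_defects(pop$records, pop$genotypes, spec, seed = 2)
  man <- bad$manifest
  pair <- man$duplicate_pairs
  expect_equal(cor(bad$genotypes$calls[pair$a, ],
                   bad$genotypes$calls[pair$b, ]), 1.0)
  cr <- animal_call_rate(bad$genotypes)
  expect_true(all(cr[man$low_call_animals] <= 0.85 + 1e-9))
  expect_true(all(cr[man$low_call_animals] < 0.90))
  expect_true(all(snp_call_rate(bad$genotypes)[man$low_call_snps] < 0.95))
  expect_true(all(snp_maf(bad$genotypes)[man$monomorphic_snps] == 0))
  chr <- bad$genotypes$map$chromosome[
    match(man$nonautosomal_snps, bad$genotypes$map$snp_id)]
  expect_true(all(chr %in% c("X", "Y", "MT")))
  counts <- table(bad$records$animal_id[bad$records$animal_id %in%
                                          man$short_lactation_cows])
  expect_true(all(counts == 3))
  # reproducible under seed
  bad2 <- inject_defects(pop$records, pop$genotypes, spec, seed = 2)
  expect_identical(bad$genotypes$calls, bad2$genotypes$calls)
  expect_identical(bad$manifest, bad2$manifest)
  # over-injection is an error
  expect_error(inject_defects(pop$records, pop$genotypes,
                              defect_spec(low_call_animals = 100)),
               "exceed")
})
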