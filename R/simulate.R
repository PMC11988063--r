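#' Simulate herd structure of a smallholder dairy population
#'
#' Draws herd sizes i.i.d. from the configured herd-size distribution
#' (default: the observed composition of a smallholder population where twoish
#' thirds of herds hold a single cow) and partitions herds among community
#' development centres (CDC). When `n_animals` is supplied, herds are drawn
#' until the target animal count is reached and the last herd is trimmed so
#' the population size is exact.
#'
#' @param config a [sim_config()].
#' @param n_animals optional exact number of animals to generate.
#' @return data.frame with columns `animal_id`, `herd_id`, `cdc_id`.
#' @export
#' @examples
#' herds <- simulate_herds(sim_config(n_herds = 20, seed = 42))
#' table(table(herds$herd_id))
simulate_herds <- function(config, n_animals = NULL) {
  validate_sim_config(config)
  p <- config$herd_size_distribution
  set.seed(config$seed)
  if (is.null(n_animals)) {
    sizes <- sample.int(length(p), config$n_herds, replace = TRUE, prob = p)
  } else {
    stopifnot(n_animals >= 1)
    sizes <- integer(0)
    while (sum(sizes) < n_animals) {
      k <- max(64L, ceiling((n_animals - sum(sizes)) / max(1e-9, sum(p * seq_along(p)))))
      sizes <- c(sizes, sample.int(length(p), k, replace = TRUE, prob = p))
    }
    keep <- which(cumsum(sizes) >= n_animals)[1]
    sizes <- sizes[seq_len(keep)]
    sizes[keep] <- sizes[keep] - (sum(sizes) - n_animals)
    if (sizes[keep] == 0L) sizes <- sizes[-keep]
  }
  n_herd <- length(sizes)
  herd_id <- sprintf("H%05d", seq_len(n_herd))
  n_cdc <- config$n_cdcs %||% max(1L, round(n_herd / 22))
  n_cdc <- max(1L, min(n_cdc, n_herd))
  cdc_of_herd <- sprintf("CDC%03d", sample(rep_len(seq_len(n_cdc), n_herd)))
  data.frame(
    animal_id = sprintf("A%06d", seq_len(sum(sizes))),
    herd_id = rep(herd_id, sizes),
    cdc_id = rep(cdc_of_herd, sizes),
    stringsAsFactors = FALSE
  )
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Per-SNP allele frequencies are drawn uniformly from the configured MAF
#' range and genotypes sampled binomial(2, p) per animal. Chromosome labels
#' are assigned cyclically over autosomes 1..29. No missingness is
#' generated; defects (missing calls, duplicates, non-autosomal markers) are
#' injected separately by [inject_defects()].
#'
#' @param config a [sim_config()].
#' @param n_animals number of animals.
#' @return a [genotype_matrix()] with attribute `"true_freq"` holding the
#'   drawn allele frequencies.
#' @export
simulate_genotypes <- function(config, n_animals) {
  validate_sim_config(config)
  stopifnot(n_animals >= 1)
  set.seed(config$seed + 1L)
  m <- config$n_snps
  p <- runif(m, config$maf_range[1], config$maf_range[2])
  calls <- matrix(rbinom(n_animals * m, 2L, rep(p, each = n_animals)),
                  nrow = n_animals, ncol = m,
                  dimnames = list(sprintf("A%06d", seq_len(n_animals)),
                                  sprintf("SNP%05d", seq_len(m))))
  gm <- genotype_matrix(calls,
                        chromosome = as.character(rep_len(1:29, m)),
                        position_bp = seq_len(m) * 1000L)
  attr(gm, "true_freq") <- p
  gm
}

#' Simulate SNP effects under a four-component mixture
#'
#' Each SNP is assigned a class by the mixture proportions; class-`k`
#' effects are normal with variance `scale_k * Va / normalizer`, where the
#' normalizer `sum_k(pi_k scale_k) * sum_j 2 p_j (1 - p_j)` makes the
#' expected genic variance equal `Va`. Class 1 effects are exactly zero.
#'
#' @param config a [sim_config()].
#' @param genotypes a [genotype_matrix()] from [simulate_genotypes()] (its
#'   observed allele frequencies set the normalizer and the centering).
#' @return list of class `ground_truth` with `true_snp_effects`,
#'   `true_component_assignments`, `true_breeding_values` (centered
#'   genotypes times effects, exactly) and `allele_freq`.
#' @export
simulate_snp_effects <- function(config, genotypes) {
  validate_sim_config(config)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  set.seed(config$seed + 2L)
  m <- n_snps(genotypes)
  pi_k <- config$mixture_proportions
  gam <- config$mixture_variance_scales
  Va <- config$variance_components$Va
  p <- allele_freq(genotypes)
  sum2pq <- sum(2 * p * (1 - p))
  classes <- sample.int(4L, m, replace = TRUE, prob = pi_k)
  beta <- numeric(m)
  if (Va > 0 && sum(pi_k * gam) > 0) {
    vk <- gam * Va / (sum(pi_k * gam) * sum2pq)
    nz <- classes > 1L
    beta[nz] <- rnorm(sum(nz), 0, sqrt(vk[classes[nz]]))
  }
  W <- sweep(genotypes$calls, 2L, 2 * p)
  bv <- drop(W %*% beta)
  if (config$exact_bv_scale && Va > 0 && stats::sd(bv) > 0) {
    sc <- sqrt(Va) / stats::sd(bv)
    beta <- beta * sc
    bv <- bv * sc
  }
  structure(list(true_snp_effects = beta,
                 true_component_assignments = classes,
                 true_breeding_values = setNames(bv, rownames(genotypes$calls)),
                 allele_freq = p),
            class = "ground_truth")
}

#' Simulate test-day fat percentage records
#'
#' Builds one record per cow, lactation and test day: a population mean of
#' 4 (fat %) plus fixed effects for lactation number, CDC and
#' year-month-by-CDC (i.i.d. normal draws), the cow's true breeding value
#' (optionally shaped over days in milk by a Legendre trajectory when the
#' configured order m > 0), a permanent-environment effect, a herd effect
#' and residual noise. Test days are equally spaced within the DIM window by
#' default.
#'
#' @param config a [sim_config()].
#' @param herds herd table from [simulate_herds()].
#' @param genotypes a [genotype_matrix()] covering the same animals.
#' @param truth a `ground_truth` from [simulate_snp_effects()].
#' @return data.frame of test-day records (`animal_id`, `herd_id`, `cdc_id`,
#'   `lactation_number`, `days_in_milk`, `year_month`, `fat_pct`) with
#'   attribute `"truth"` extended by the drawn fixed and environmental
#'   effects.
#' @export
simulate_phenotypes <- function(config, herds, genotypes, truth) {
  validate_sim_config(config)
  stopifnot(inherits(truth, "ground_truth"))
  n <- nrow(herds)
  if (n_animals(genotypes) != n || length(truth$true_breeding_values) != n)
    stop("herds, genotypes and truth must cover the same animals",
         call. = FALSE)
  vc <- config$variance_components
  if (is.null(vc$Ve)) stop("variance components missing Ve", call. = FALSE)
  set.seed(config$seed + 3L)

  k <- config$records_per_lactation
  dim_days <- round(seq(config$dim_window[1], config$dim_window[2],
                        length.out = k))
  n_lac <- config$n_lactations
  # fixed-effect draws
  lact_eff <- setNames(c(0, rnorm(max(0L, n_lac - 1L), 0, config$fixed_effect_sd)),
                       seq_len(n_lac))
  cdcs <- sort(unique(herds$cdc_id))
  cdc_eff <- setNames(rnorm(length(cdcs), 0, config$fixed_effect_sd), cdcs)
  # calving month per cow-lactation; year-month token = calving month + DIM
  pe <- rnorm(n, 0, sqrt(vc$Vpe))
  herd_ids <- sort(unique(herds$herd_id))
  herd_eff <- setNames(rnorm(length(herd_ids), 0, sqrt(vc$Vherd)), herd_ids)

  calving <- matrix(sample.int(24L, n * n_lac, replace = TRUE), n, n_lac)
  rec <- vector("list", n_lac)
  bv <- truth$true_breeding_values
  if (config$legendre_order > 0L) {
    # genetic trajectory: bv scaled by a mild first-order Legendre shape
    # whose window average is ~1, so var of the mean trajectory stays Va
    phi <- legendre_covariates(dim_days, config$legendre_order,
                               config$dim_window)
    shape <- 1 + 0.3 * phi[, 2]
  } else {
    shape <- rep(1, k)
  }
  for (l in seq_len(n_lac)) {
    dd <- dim_days
    if (config$dim_jitter_sd > 0) {
      dd <- round(pmin(pmax(dim_days + rnorm(k, 0, config$dim_jitter_sd),
                            config$dim_window[1]), config$dim_window[2]))
    }
    ym <- outer(calving[, l], ceiling(dd / 30.44), "+")  # month index
    e <- matrix(rnorm(n * k, 0, sqrt(vc$Ve)), n, k)
    y <- 4 + lact_eff[[l]] + cdc_eff[herds$cdc_id] +
      outer(bv, shape) + pe + herd_eff[herds$herd_id] + e
    rec[[l]] <- data.frame(
      animal_id = rep(herds$animal_id, k),
      herd_id = rep(herds$herd_id, k),
      cdc_id = rep(herds$cdc_id, k),
      lactation_number = l,
      days_in_milk = rep(dd, each = n),
      year_month = sprintf("YM%02d", as.vector(ym)),
      fat_pct = as.vector(y),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rec)
  # year-month-by-CDC interaction effects, drawn per observed cell
  cells <- unique(paste(out$year_month, out$cdc_id, sep = ":"))
  ymcdc_eff <- setNames(rnorm(length(cells), 0, config$fixed_effect_sd), cells)
  out$fat_pct <- out$fat_pct +
    ymcdc_eff[paste(out$year_month, out$cdc_id, sep = ":")]
  rownames(out) <- NULL
  truth$fixed_effects <- list(mean = 4, lactation = lact_eff, cdc = cdc_eff,
                              year_month_cdc = ymcdc_eff)
  truth$permanent_env <- setNames(pe, herds$animal_id)
  truth$herd_effects <- herd_eff
  attr(out, "truth") <- truth
  out
}

#' Simulate a complete population
#'
#' Convenience wrapper chaining [simulate_herds()], [simulate_genotypes()],
#' [simulate_snp_effects()] and [simulate_phenotypes()].
#'
#' @param config a [sim_config()].
#' @param n_animals optional exact animal count (see [simulate_herds()]).
#' @return list with `herds`, `genotypes`, `truth`, `records`.
#' @export
simulate_population <- function(config, n_animals = NULL) {
  herds <- simulate_herds(config, n_animals)
  genotypes <- simulate_genotypes(config, nrow(herds))
  rownames(genotypes$calls) <- herds$animal_id
  if (!is.null(genotypes$gc_score)) rownames(genotypes$gc_score) <- herds$animal_id
  truth <- simulate_snp_effects(config, genotypes)
  records <- simulate_phenotypes(config, herds, genotypes, truth)
  list(herds = herds, genotypes = genotypes,
       truth = attr(records, "truth"), records = records)
}
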