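#' Simulation configuration for a synthetic smallholder dairy population
#'
#' Bundles every parameter the synthetic-data generator needs. Defaults
#' reproduce the study conditions of a smallholder crossbred dairy recording
#' scheme: herd sizes dominated by one- and two-cow herds, at least four
#' monthly fat records per lactation taken between 8 and 340 days in milk,
#' additive genetic variance 0.012 and residual variance 0.106 (fat%^2), and
#' 50K-style biallelic genotypes whose effects follow a four-component
#' BayesR-type normal mixture (one component exactly zero).
#'
#' @param n_herds number of herds to simulate (ignored when a target animal
#'   count is passed to [simulate_herds()]).
#' @param herd_size_distribution probability vector over herd sizes
#'   `1..length(.)`; must sum to 1. Default is the observed herd-count
#'   composition of a 1,260-herd smallholder population (66.6% single-cow).
#' @param n_cdcs number of community development centres (CDC); herds are
#'   partitioned among CDCs. A CDC is the administrative grouping of farms
#'   used as a fixed effect. The default (`NULL`) assigns one CDC per ~22
#'   realized herds, the density observed in the smallholder recording
#'   scheme (75 CDCs for 1,659 farms).
#' @param n_snps number of biallelic SNPs.
#' @param maf_range interval in (0, 0.5] from which per-SNP allele
#'   frequencies are drawn uniformly.
#' @param legendre_order order m >= 0 of the Legendre polynomial used for
#'   the genetic trajectory over days in milk (m = 0: flat trajectory).
#' @param variance_components named list `Va`, `Vpe`, `Vherd`, `Ve` in
#'   fat%^2. `Va` is the variance of true breeding values, `Vpe` the
#'   permanent-environment variance, `Vherd` the herd variance, `Ve` the
#'   test-day residual variance.
#' @param mixture_proportions probability 4-vector over SNP-effect classes;
#'   class 1 is the null (zero-effect) class.
#' @param mixture_variance_scales 4-vector of per-class effect-variance
#'   scales as fractions of the total genic variance; class 1 must be 0.
#'   Default `(0, 1e-4, 1e-3, 1e-2)`.
#' @param records_per_lactation test-day records per cow per lactation.
#' @param dim_window closed days-in-milk window, default `c(8, 340)`.
#' @param n_lactations lactations per cow.
#' @param fixed_effect_sd standard deviation (fat%) of the i.i.d. normal
#'   draws used for lactation, CDC and year-month-by-CDC fixed effects.
#' @param dim_jitter_sd SD in days of optional jitter around the equally
#'   spaced test days; 0 (default) keeps them equally spaced.
#' @param exact_bv_scale logical; rescale drawn SNP effects so the realized
#'   variance of true breeding values equals `Va` exactly (standard
#'   simulation calibration).
#' @param seed integer master seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_population()], [simulate_herds()]
#' @export
#' @examples
#' cfg <- sim_config(n_herds = 50, n_snps = 200, seed = 1)
#' cfg$variance_components$Va
sim_config <- function(n_herds = 1260,
                       herd_size_distribution = c(839, 297, 79, 21, 15, 5, 4) / 1260,
                       n_cdcs = NULL,
                       n_snps = 5000,
                       maf_range = c(0.05, 0.5),
                       legendre_order = 0L,
                       variance_components = list(Va = 0.012, Vpe = 0,
                                                  Vherd = 0, Ve = 0.106),
                       mixture_proportions = c(0.95, 0.03, 0.015, 0.005),
                       mixture_variance_scales = c(0, 1e-4, 1e-3, 1e-2),
                       records_per_lactation = 8L,
                       dim_window = c(8L, 340L),
                       n_lactations = 1L,
                       fixed_effect_sd = 0.1,
                       dim_jitter_sd = 0,
                       exact_bv_scale = TRUE,
                       seed = 1L) {
  cfg <- list(n_herds = as.integer(n_herds),
              herd_size_distribution = herd_size_distribution,
              n_cdcs = if (!is.null(n_cdcs)) as.integer(n_cdcs),
              n_snps = as.integer(n_snps),
              maf_range = maf_range,
              legendre_order = as.integer(legendre_order),
              variance_components = variance_components,
              mixture_proportions = mixture_proportions,
              mixture_variance_scales = mixture_variance_scales,
              records_per_lactation = as.integer(records_per_lactation),
              dim_window = as.numeric(dim_window),
              n_lactations = as.integer(n_lactations),
              fixed_effect_sd = fixed_effect_sd,
              dim_jitter_sd = dim_jitter_sd,
              exact_bv_scale = isTRUE(exact_bv_scale),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(cfg$herd_size_distribution) < 1L)
    stop("herd_size_distribution must be non-empty", call. = FALSE)
  if (any(cfg$herd_size_distribution < 0))
    stop("herd_size_distribution must be non-negative", call. = FALSE)
  if (abs(sum(cfg$herd_size_distribution) - 1) > 1e-12)
    stop("herd_size_distribution must sum to 1 (within 1e-12)", call. = FALSE)
  if (abs(sum(cfg$mixture_proportions) - 1) > 1e-12)
    stop("mixture_proportions must sum to 1 (within 1e-12)", call. = FALSE)
  if (length(cfg$mixture_proportions) != 4L ||
      length(cfg$mixture_variance_scales) != 4L)
    stop("mixture proportions and variance scales must have length 4",
         call. = FALSE)
  if (any(cfg$mixture_variance_scales < 0))
    stop("mixture_variance_scales must be non-negative", call. = FALSE)
  if (cfg$mixture_variance_scales[1] != 0)
    stop("class-1 mixture variance scale must be exactly 0", call. = FALSE)
  vc <- cfg$variance_components
  if (!all(c("Va", "Vpe", "Vherd", "Ve") %in% names(vc)))
    stop("variance_components must name Va, Vpe, Vherd, Ve", call. = FALSE)
  if (any(unlist(vc) < 0))
    stop("variance components must be >= 0", call. = FALSE)
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2])
    stop("maf_range must lie within (0, 0.5]", call. = FALSE)
  if (cfg$n_snps < 1L || cfg$n_herds < 1L)
    stop("n_snps and n_herds must be positive", call. = FALSE)
  if (cfg$records_per_lactation < 1L || cfg$n_lactations < 1L)
    stop("records_per_lactation and n_lactations must be >= 1", call. = FALSE)
  if (cfg$legendre_order < 0L)
    stop("legendre_order must be >= 0", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_herds, "herds,",
      if (is.null(x$n_cdcs)) "auto" else x$n_cdcs, "CDCs,",
      x$n_snps, "SNPs\n")
  cat("  herd sizes 1..", length(x$herd_size_distribution),
      " p = ", paste(signif(x$herd_size_distribution, 3), collapse = ", "),
      "\n", sep = "")
  vc <- x$variance_components
  cat(sprintf("  Va=%.4g Vpe=%.4g Vherd=%.4g Ve=%.4g (fat%%^2)\n",
              vc$Va, vc$Vpe, vc$Vherd, vc$Ve))
  cat("  records/lactation =", x$records_per_lactation,
      " DIM window [", x$dim_window[1], ",", x$dim_window[2], "]",
      " lactations =", x$n_lactations, "\n")
  invisible(x)
}

#' Write or read a simulation configuration as YAML
#'
#' @param cfg a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write configs", call. = FALSE)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configs", call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(sim_config, raw[intersect(names(raw), names(formals(sim_config)))])
}
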