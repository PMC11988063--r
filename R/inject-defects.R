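#' Defect specification for QC exercising
#'
#' Counts of defects to inject into a clean simulated population so that
#' every quality-control filter has known targets. All counts default to 0.
#'
#' @param duplicate_animals genotype rows copied onto other animals (the
#'   duplicate-detection filter must flag the pair).
#' @param low_call_animals animals whose genotype call rate is forced to
#'   `animal_call_rate_value` (below the 0.90 retention threshold).
#' @param low_call_snps SNPs whose call rate is forced to
#'   `snp_call_rate_value` (below the 0.95 threshold).
#' @param monomorphic_snps SNPs set to a constant call (MAF 0).
#' @param nonautosomal_snps SNPs relabelled to X/Y/MT chromosomes.
#' @param outlier_cows cows whose records are shifted up by `outlier_shift`
#'   fat% (the 3-SD cow-mean filter must remove them).
#' @param residual_outlier_records single records shifted by `outlier_shift`.
#' @param short_lactation_cows cows reduced to 3 in-window records per
#'   lactation (below the 4-record minimum).
#' @param animal_call_rate_value,snp_call_rate_value,outlier_shift defect
#'   magnitudes.
#' @return list of class `defect_spec`.
#' @export
defect_spec <- function(duplicate_animals = 0L, low_call_animals = 0L,
                        low_call_snps = 0L, monomorphic_snps = 0L,
                        nonautosomal_snps = 0L, outlier_cows = 0L,
                        residual_outlier_records = 0L,
                        short_lactation_cows = 0L,
                        animal_call_rate_value = 0.85,
                        snp_call_rate_value = 0.90,
                        outlier_shift = 6) {
  out <- as.list(environment())
  class(out) <- "defect_spec"
  out
}

#' Inject known defects into a clean simulated population
#'
#' Corrupts copies of the phenotype records and genotypes so that each QC
#' filter has a known, exact removal target, and returns a manifest listing
#' which entities each filter must remove. Injection is reproducible under
#' `seed`. Defect groups target disjoint entities so the manifest is exact.
#'
#' @param records test-day record data.frame.
#' @param genotypes a [genotype_matrix()].
#' @param spec a [defect_spec()].
#' @param seed integer seed.
#' @return list with corrupted `records`, `genotypes`, and `manifest` (a
#'   list of entity-id vectors per filter).
#' @export
inject_defects <- function(records, genotypes, spec = defect_spec(),
                           seed = 1L) {
  stopifnot(inherits(spec, "defect_spec"), inherits(genotypes, "genotype_matrix"))
  set.seed(seed)
  gm <- genotypes
  rec <- records
  animals <- rownames(gm$calls)
  snps <- colnames(gm$calls)
  n <- length(animals); m <- length(snps)

  n_animal_defects <- spec$duplicate_animals * 2L + spec$low_call_animals +
    spec$outlier_cows + spec$short_lactation_cows
  if (n_animal_defects > n)
    stop("requested animal defects exceed population size", call. = FALSE)
  n_snp_defects <- spec$low_call_snps + spec$monomorphic_snps +
    spec$nonautosomal_snps
  if (n_snp_defects > m)
    stop("requested SNP defects exceed number of SNPs", call. = FALSE)

  pool_a <- sample(animals)
  take_a <- function(k) {
    out <- pool_a[seq_len(k)]
    pool_a <<- pool_a[-seq_len(k)]
    out
  }
  pool_s <- sample(snps)
  take_s <- function(k) {
    out <- pool_s[seq_len(k)]
    pool_s <<- pool_s[-seq_len(k)]
    out
  }
  manifest <- list()

  # duplicates: copy source genotype row onto target; target is the one to
  # drop when call rates tie is broken by id order -- record the pair
  if (spec$duplicate_animals > 0L) {
    src <- take_a(spec$duplicate_animals)
    dst <- take_a(spec$duplicate_animals)
    gm$calls[dst, ] <- gm$calls[src, ]
    manifest$duplicate_pairs <- data.frame(a = src, b = dst,
                                           stringsAsFactors = FALSE)
  }
  if (spec$low_call_animals > 0L) {
    ids <- take_a(spec$low_call_animals)
    n_miss <- ceiling((1 - spec$animal_call_rate_value) * m)
    for (id in ids)
      gm$calls[id, sample.int(m, n_miss)] <- NA
    manifest$low_call_animals <- ids
  }
  if (spec$low_call_snps > 0L) {
    ids <- take_s(spec$low_call_snps)
    n_miss <- ceiling((1 - spec$snp_call_rate_value) * n)
    for (id in ids)
      gm$calls[sample.int(n, n_miss), id] <- NA
    manifest$low_call_snps <- ids
  }
  if (spec$monomorphic_snps > 0L) {
    ids <- take_s(spec$monomorphic_snps)
    gm$calls[, ids] <- 0L
    manifest$monomorphic_snps <- ids
  }
  if (spec$nonautosomal_snps > 0L) {
    ids <- take_s(spec$nonautosomal_snps)
    gm$map$chromosome[match(ids, gm$map$snp_id)] <-
      sample(c("X", "Y", "MT"), length(ids), replace = TRUE)
    manifest$nonautosomal_snps <- ids
  }
  if (spec$outlier_cows > 0L) {
    ids <- take_a(spec$outlier_cows)
    sel <- rec$animal_id %in% ids
    rec$fat_pct[sel] <- rec$fat_pct[sel] + spec$outlier_shift
    manifest$outlier_cows <- ids
  }
  if (spec$short_lactation_cows > 0L) {
    ids <- take_a(spec$short_lactation_cows)
    keep <- rep(TRUE, nrow(rec))
    for (id in ids) {
      for (l in unique(rec$lactation_number[rec$animal_id == id])) {
        idx <- which(rec$animal_id == id & rec$lactation_number == l)
        if (length(idx) > 3L) keep[idx[-seq_len(3L)]] <- FALSE
      }
    }
    rec <- rec[keep, , drop = FALSE]
    manifest$short_lactation_cows <- ids
  }
  if (spec$residual_outlier_records > 0L) {
    # shift single records of otherwise-clean cows; keep the per-cow mean
    # shift small enough not to trip the cow-outlier filter
    elig <- which(!(rec$animal_id %in% unlist(manifest[c("outlier_cows",
                                                         "short_lactation_cows")])))
    idx <- sample(elig, spec$residual_outlier_records)
    rec$fat_pct[idx] <- rec$fat_pct[idx] + spec$outlier_shift
    manifest$residual_outlier_records <- idx
  }
  rownames(rec) <- NULL
  list(records = rec, genotypes = gm, manifest = manifest)
}
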