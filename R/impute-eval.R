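#' Squared correlation of allele frequencies between two panels
#'
#' The imputation-quality metric comparing allele frequencies estimated on a
#' low-density and a high-density genotyping panel over shared SNPs.
#'
#' @param freq_low,freq_high allele-frequency vectors of equal length over
#'   the shared SNPs, values in `[0, 1]`.
#' @return squared Pearson correlation in `[0, 1]`.
#' @export
#' @examples
#' allele_freq_r2(c(0.1, 0.2, 0.3, 0.4), c(0.4, 0.3, 0.2, 0.1))  # 1
allele_freq_r2 <- function(freq_low, freq_high) {
  if (length(freq_low) != length(freq_high))
    stop("frequency vectors must have equal length", call. = FALSE)
  if (length(freq_low) < 3L)
    stop("need at least 3 shared SNPs", call. = FALSE)
  if (any(freq_low < 0 | freq_low > 1 | freq_high < 0 | freq_high > 1,
          na.rm = TRUE))
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  if (sd(freq_low) == 0 || sd(freq_high) == 0)
    stop("correlation undefined for a constant frequency vector",
         call. = FALSE)
  cor(freq_low, freq_high)^2
}

#' Naive mean imputation of missing genotype calls
#'
#' Replaces each missing call by the SNP's mean observed genotype, a
#' real-valued dosage in `[0, 2]`. This is the baseline imputer used for
#' masking evaluation; it preserves observed allele frequencies exactly.
#'
#' @param gm a [genotype_matrix()]; every SNP must have at least one
#'   observed call.
#' @return list-like `genotype_matrix` whose `calls` may hold fractional
#'   dosages.
#' @export
mean_imputer <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mu <- colMeans(gm$calls, na.rm = TRUE)
  if (any(is.nan(mu)))
    stop("SNP(s) with no observed calls cannot be mean-imputed: ",
         paste(head(colnames(gm$calls)[is.nan(mu)]), collapse = ", "),
         call. = FALSE)
  calls <- gm$calls
  idx <- which(is.na(calls), arr.ind = TRUE)
  if (nrow(idx)) calls[idx] <- mu[idx[, 2]]
  out <- gm
  out$calls <- calls
  out
}

#' Masking concordance of an imputer
#'
#' Hides a random fraction of the observed calls, re-imputes them, and
#' compares the re-imputed dosages (rounded to the nearest genotype class,
#' ties away from zero) with the hidden truth. Masks that would leave a SNP
#' with no observed call are re-drawn a bounded number of times.
#'
#' @param gm a [genotype_matrix()] (complete or partially missing).
#' @param mask_fraction fraction of observed calls to hide, in (0, 1).
#' @param imputer function mapping a `genotype_matrix` to a completed one
#'   (default [mean_imputer()]).
#' @param seed integer seed; identical seeds give identical masks.
#' @param max_retries bound on mask re-draws.
#' @return list with `concordance` (overall fraction of matches), `per_snp_r2`
#'   (squared correlation of imputed dosage vs truth per masked SNP; `NA`
#'   where undefined) and `n_masked`.
#' @export
masking_concordance <- function(gm, mask_fraction, imputer = mean_imputer,
                                seed = 1L, max_retries = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (mask_fraction <= 0 || mask_fraction >= 1)
    stop("mask_fraction must lie in (0, 1)", call. = FALSE)
  set.seed(seed)
  obs <- which(!is.na(gm$calls))
  n_mask <- max(1L, floor(mask_fraction * length(obs)))
  for (try in seq_len(max_retries)) {
    mask <- sample(obs, n_mask)
    masked <- gm$calls
    masked[mask] <- NA
    ok <- all(colSums(!is.na(masked)) > 0)
    if (ok) break
    warning("mask left an all-missing SNP; re-drawing")
  }
  if (!ok) stop("could not draw a mask keeping every SNP observed",
                call. = FALSE)
  gm2 <- gm
  gm2$calls <- masked
  imputed <- imputer(gm2)
  truth <- gm$calls[mask]
  dosage <- imputed$calls[mask]
  called <- pmin(2, pmax(0, floor(dosage + 0.5)))  # ties away from zero
  snp_of <- ((mask - 1L) %/% nrow(gm$calls)) + 1L
  per_snp <- tapply(seq_along(mask), snp_of, function(ii) {
    if (length(ii) < 2L || sd(truth[ii]) == 0 || sd(dosage[ii]) == 0)
      return(NA_real_)
    cor(truth[ii], dosage[ii])^2
  })
  list(concordance = mean(called == truth),
       per_snp_r2 = per_snp,
       n_masked = n_mask)
}
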