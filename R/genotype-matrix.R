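#' Construct a genotype matrix object
#'
#' Container for animals-by-SNPs genotype calls coded 0/1/2 (count of the
#' alternate allele) with `NA` for missing, plus per-SNP metadata
#' (chromosome label in `1..29`, `X`, `Y`, `MT`; base-pair position) and an
#' optional per-call GenCall quality score in `[0, 1]`.
#'
#' @param calls numeric/integer matrix, animals in rows (rownames = animal
#'   ids), SNPs in columns (colnames = SNP ids); values in `{0,1,2,NA}`.
#' @param chromosome character/integer vector of per-SNP chromosome labels.
#' @param position_bp integer vector of per-SNP positions.
#' @param gc_score optional numeric matrix of per-call GenCall scores,
#'   dimensions matching `calls`.
#' @return An object of class `genotype_matrix`: list with elements `calls`,
#'   `map` (data.frame: snp_id, chromosome, position_bp) and `gc_score`.
#' @export
genotype_matrix <- function(calls, chromosome, position_bp = seq_len(ncol(calls)),
                            gc_score = NULL) {
  calls <- as.matrix(calls)
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("A", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- paste0("SNP", seq_len(ncol(calls)))
  if (length(chromosome) != ncol(calls))
    stop("chromosome must have one label per SNP", call. = FALSE)
  if (length(position_bp) != ncol(calls))
    stop("position_bp must have one entry per SNP", call. = FALSE)
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  if (!is.null(gc_score)) {
    gc_score <- as.matrix(gc_score)
    if (!all(dim(gc_score) == dim(calls)))
      stop("gc_score dimensions must match calls", call. = FALSE)
  }
  structure(list(
    calls = calls,
    map = data.frame(snp_id = colnames(calls),
                     chromosome = as.character(chromosome),
                     position_bp = as.integer(position_bp),
                     stringsAsFactors = FALSE),
    gc_score = gc_score
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "animals x", ncol(x$calls), "SNPs\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%;  gc_score: %s\n", 100 * miss,
              if (is.null(x$gc_score)) "absent" else "present"))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param x a `genotype_matrix`.
#' @export
n_animals <- function(x) nrow(x$calls)

#' @rdname genotype_matrix
#' @export
n_snps <- function(x) ncol(x$calls)

#' Per-animal and per-SNP call rates and allele frequencies
#'
#' `animal_call_rate`/`snp_call_rate` return the fraction of non-missing
#' calls per animal/SNP. `allele_freq` returns the alternate-allele
#' frequency per SNP among observed calls; `snp_maf` folds it to the minor
#' allele frequency.
#'
#' @param x a [genotype_matrix()].
#' @return named numeric vector.
#' @export
animal_call_rate <- function(x) rowMeans(!is.na(x$calls))

#' @rdname animal_call_rate
#' @export
snp_call_rate <- function(x) colMeans(!is.na(x$calls))

#' @rdname animal_call_rate
#' @export
allele_freq <- function(x) colMeans(x$calls, na.rm = TRUE) / 2

#' @rdname animal_call_rate
#' @export
snp_maf <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}

# subset helper keeping map/gc_score in step
subset_genotypes <- function(x, animals = NULL, snps = NULL) {
  if (is.null(animals)) animals <- seq_len(nrow(x$calls))
  if (is.null(snps)) snps <- seq_len(ncol(x$calls))
  genotype_matrix(x$calls[animals, snps, drop = FALSE],
                  chromosome = x$map$chromosome[snps],
                  position_bp = x$map$position_bp[snps],
                  gc_score = if (!is.null(x$gc_score))
                    x$gc_score[animals, snps, drop = FALSE])
}
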