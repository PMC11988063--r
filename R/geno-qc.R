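#' Mask calls below a GenCall score threshold
#'
#' Calls with GenCall score `<= threshold` are set to missing. When no
#' scores are attached the matrix passes through unchanged with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param threshold GenCall score threshold (default 0.15; retention is
#'   strictly "higher than").
#' @return a [genotype_matrix()].
#' @export
apply_gc_score <- function(gm, threshold = 0.15) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$gc_score)) {
    warning("no GenCall scores attached; GC-score masking skipped")
    return(gm)
  }
  gm$calls[gm$gc_score <= threshold] <- NA
  gm
}

#' Detect and prune duplicate animals by genotype correlation
#'
#' Pairwise Pearson correlation of genotype calls over shared non-missing
#' SNPs; pairs with correlation above `r_threshold` are flagged as
#' duplicates. Within each duplicate group the animal with the highest call
#' rate is retained (ties broken by animal id order). Animals with no
#' genotype overlap with any other animal are excluded from pairing.
#'
#' @param gm a [genotype_matrix()] with at least 2 animals.
#' @param r_threshold correlation threshold (default 0.98, strict).
#' @return list with pruned `genotypes`, `pairs` (data.frame of flagged
#'   pairs with their correlation), `removed` animal ids and a `ledger` row.
#' @export
detect_duplicates <- function(gm, r_threshold = 0.98) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_animals(gm)
  if (n < 2L) stop("need at least 2 animals", call. = FALSE)
  suppressWarnings(
    cc <- cor(t(gm$calls), use = "pairwise.complete.obs")
  )
  overlap <- (!is.na(gm$calls)) %*% t(!is.na(gm$calls))
  cc[overlap == 0] <- NA  # no shared calls: cannot judge
  diag(cc) <- NA
  idx <- which(cc > r_threshold & upper.tri(cc), arr.ind = TRUE)
  ids <- rownames(gm$calls)
  pairs <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                      r = cc[idx], stringsAsFactors = FALSE)
  removed <- character(0)
  if (nrow(pairs)) {
    # connected components of the duplicate graph; keep best call rate
    cr <- animal_call_rate(gm)
    comp <- seq_len(n); names(comp) <- ids
    for (k in seq_len(nrow(pairs))) {
      ca <- comp[pairs$a[k]]; cb <- comp[pairs$b[k]]
      comp[comp == cb] <- ca
    }
    for (g in unique(comp[c(pairs$a, pairs$b)])) {
      members <- ids[comp == g]
      keep <- members[order(-cr[members], members)][1]
      removed <- c(removed, setdiff(members, keep))
    }
  }
  keep_idx <- !(ids %in% removed)
  list(genotypes = subset_genotypes(gm, animals = keep_idx),
       pairs = pairs, removed = removed,
       ledger = qc_ledger_entry("duplicate animals",
                                sprintf("genotype r > %g", r_threshold),
                                screened = n, dropped = length(removed),
                                unit = "animal"))
}

#' Filter animals by genotype call rate
#'
#' Animals whose fraction of non-missing calls is not strictly higher than
#' `threshold` are removed.
#'
#' @param gm a [genotype_matrix()].
#' @param threshold call-rate threshold (default 0.90).
#' @return list with filtered `genotypes`, `removed` ids and a `ledger` row.
#' @export
filter_animal_call_rate <- function(gm, threshold = 0.90) {
  stopifnot(inherits(gm, "genotype_matrix"))
  cr <- animal_call_rate(gm)
  keep <- cr > threshold
  list(genotypes = subset_genotypes(gm, animals = keep),
       removed = rownames(gm$calls)[!keep],
       ledger = qc_ledger_entry("animal call rate",
                                sprintf("> %g", threshold),
                                screened = length(cr), retained = sum(keep),
                                unit = "animal"))
}

#' Filter SNPs by call rate and minor allele frequency
#'
#' Per-SNP call rate and MAF are computed over the currently retained
#' animals; SNPs failing either the call-rate or the MAF threshold are
#' dropped. The ledger reports the combined drop, as the two criteria are
#' screened together.
#'
#' @param gm a [genotype_matrix()] with at least 1 animal.
#' @param call_rate_threshold SNP call-rate threshold (default 0.95).
#' @param maf_threshold MAF threshold (default 0.01); both strict.
#' @return list with filtered `genotypes`, `removed` SNP ids and a `ledger`
#'   row.
#' @export
filter_snp_quality <- function(gm, call_rate_threshold = 0.95,
                               maf_threshold = 0.01) {
  stopifnot(inherits(gm, "genotype_matrix"), n_animals(gm) >= 1L)
  cr <- snp_call_rate(gm)
  maf <- snp_maf(gm)
  maf[is.na(maf)] <- 0  # all-missing SNP: MAF undefined, fails
  keep <- cr > call_rate_threshold & maf > maf_threshold
  list(genotypes = subset_genotypes(gm, snps = keep),
       removed = colnames(gm$calls)[!keep],
       ledger = qc_ledger_entry("SNP call rate and MAF",
                                sprintf("call rate > %g, MAF > %g",
                                        call_rate_threshold, maf_threshold),
                                screened = length(cr), retained = sum(keep),
                                unit = "snp"))
}

#' Restrict to autosomal SNPs
#'
#' SNPs on chromosomes outside 1..`n_autosomes` (X, Y, MT) are removed.
#'
#' @param gm a [genotype_matrix()] with chromosome labels.
#' @param n_autosomes autosome count (29 for cattle).
#' @return list with filtered `genotypes`, `removed` SNP ids and a `ledger`
#'   row.
#' @export
filter_autosomes <- function(gm, n_autosomes = 29L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  chr <- gm$map$chromosome
  known <- c(as.character(seq_len(n_autosomes)), "X", "Y", "MT")
  if (any(!chr %in% known))
    stop("unrecognized chromosome labels: ",
         paste(unique(chr[!chr %in% known]), collapse = ", "), call. = FALSE)
  keep <- chr %in% as.character(seq_len(n_autosomes))
  list(genotypes = subset_genotypes(gm, snps = keep),
       removed = colnames(gm$calls)[!keep],
       ledger = qc_ledger_entry("autosomal markers",
                                "remove X, Y, MT markers",
                                screened = length(chr), retained = sum(keep),
                                unit = "snp"))
}

#' Run the full genotypic quality-control sequence
#'
#' Stages run in order: GenCall-score masking (when scores are present),
#' duplicate-animal pruning, animal call rate, SNP call rate / MAF, autosome
#' restriction. Each later stage recomputes its statistics on the survivors
#' of the earlier ones, and the cumulative ledger makes the effect of each
#' stage auditable.
#'
#' @param gm a [genotype_matrix()].
#' @param gc_threshold GenCall score threshold (0.15).
#' @param r_threshold duplicate correlation threshold (0.98).
#' @param animal_call_rate animal call-rate threshold (0.90).
#' @param snp_call_rate SNP call-rate threshold (0.95).
#' @param maf MAF threshold (0.01).
#' @param n_autosomes autosome count (29).
#' @return list with final `genotypes`, cumulative `ledger`, and `removed`
#'   (list of entity ids per stage).
#' @export
run_geno_qc <- function(gm, gc_threshold = 0.15, r_threshold = 0.98,
                        animal_call_rate = 0.90, snp_call_rate = 0.95,
                        maf = 0.01, n_autosomes = 29L) {
  if (!is.null(gm$gc_score)) gm <- apply_gc_score(gm, gc_threshold)
  s1 <- detect_duplicates(gm, r_threshold)
  s2 <- filter_animal_call_rate(s1$genotypes, animal_call_rate)
  s3 <- filter_snp_quality(s2$genotypes, snp_call_rate, maf)
  s4 <- filter_autosomes(s3$genotypes, n_autosomes)
  list(genotypes = s4$genotypes,
       ledger = bind_ledgers(s1$ledger, s2$ledger, s3$ledger, s4$ledger),
       removed = list(duplicates = s1$removed,
                      low_call_animals = s2$removed,
                      low_quality_snps = s3$removed,
                      nonautosomal_snps = s4$removed))
}

#' Compose final retained counts from a QC ledger
#'
#' Sums drops per unit (animal/SNP) against the first screened count of
#' that unit. This reproduces cumulative retention also when ledger rows
#' report marginal screens from a common base, as published QC summaries
#' often do.
#'
#' @param ledger a `qc_ledger` data.frame with a `unit` column.
#' @return named list with retained `animals` and `snps`.
#' @export
#' @examples
#' led <- rbind(
#'   qc_ledger_entry("duplicates", "r > 0.98", 1478, dropped = 0, unit = "animal"),
#'   qc_ledger_entry("animal call rate", "> 0.90", 1478, dropped = 1, unit = "animal"),
#'   qc_ledger_entry("SNP call rate and MAF", "> 0.95 / > 0.01", 49911,
#'                   dropped = 4229, unit = "snp"),
#'   qc_ledger_entry("autosomes", "remove X/Y/MT", 49911, dropped = 9089,
#'                   unit = "snp"))
#' qc_ledger_compose(led)  # 1477 animals, 36593 SNPs
qc_ledger_compose <- function(ledger) {
  led <- as.data.frame(ledger)
  per_unit <- function(u) {
    rows <- led[led$unit == u, , drop = FALSE]
    if (!nrow(rows)) return(NA_integer_)
    rows$screened[1] - sum(rows$dropped)
  }
  list(animals = per_unit("animal"), snps = per_unit("snp"))
}
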