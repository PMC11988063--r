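#' Read test-day phenotype records from CSV
#'
#' Expects columns `animal_id`, `herd_id`, `cdc_id`, `lactation_number`,
#' `days_in_milk`, `year_month`, `fat_pct`. Malformed rows (non-numeric fat
#' percentage or days in milk, non-positive fat) are collected into a
#' reject report attached as attribute `"rejects"`, not silently dropped.
#'
#' @param path CSV file path.
#' @return data.frame of typed records with a `"rejects"` attribute.
#' @export
read_phenotypes <- function(path) {
  need <- c("animal_id", "herd_id", "cdc_id", "lactation_number",
            "days_in_milk", "year_month", "fat_pct")
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("phenotype file lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  fat <- suppressWarnings(as.numeric(raw$fat_pct))
  dim_ <- suppressWarnings(as.integer(raw$days_in_milk))
  lact <- suppressWarnings(as.integer(raw$lactation_number))
  ok <- !is.na(fat) & fat > 0 & !is.na(dim_) & dim_ >= 1 &
    !is.na(lact) & lact >= 1
  out <- data.frame(animal_id = raw$animal_id[ok],
                    herd_id = raw$herd_id[ok],
                    cdc_id = raw$cdc_id[ok],
                    lactation_number = lact[ok],
                    days_in_milk = dim_[ok],
                    year_month = raw$year_month[ok],
                    fat_pct = fat[ok],
                    stringsAsFactors = FALSE)
  rejects <- cbind(row = which(!ok), raw[!ok, , drop = FALSE])
  attr(out, "rejects") <- rejects
  out
}

#' @rdname read_phenotypes
#' @param records record data.frame.
#' @export
write_phenotypes <- function(records, path) {
  cols <- c("animal_id", "herd_id", "cdc_id", "lactation_number",
            "days_in_milk", "year_month", "fat_pct")
  write.csv(records[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes from a PLINK PED/MAP pair
#'
#' The MAP file gives per-SNP chromosome, id, genetic and physical
#' position; the PED file one line per animal (`FID IID PAT MAT SEX PHENO`
#' then two allele characters per SNP). Calls are coded as the count of the
#' lexicographically larger allele at each SNP (the writer emits alleles
#' A/B, so write/read round-trips are exact); the missing code `0 0`
#' becomes `NA`.
#'
#' @param ped_path,map_path file paths; `map_path` defaults to `ped_path`
#'   with the extension swapped.
#' @return a [genotype_matrix()].
#' @export
read_genotypes_ped <- function(ped_path,
                               map_path = sub("\\.ped$", ".map", ped_path)) {
  map <- read.table(map_path, stringsAsFactors = FALSE,
                    col.names = c("chromosome", "snp_id", "cm", "position_bp"))
  ped <- read.table(ped_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("PED/MAP mismatch: expected ", 6 + 2 * m, " PED columns, found ",
         ncol(ped), call. = FALSE)
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(ped), m)
  for (j in seq_len(m)) {
    alleles <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    if (length(alleles) > 2)
      stop("SNP ", map$snp_id[j], " has >2 alleles", call. = FALSE)
    alt <- if (length(alleles)) alleles[length(alleles)] else NA_character_
    obs <- a1[, j] != "0" & a2[, j] != "0"
    calls[obs, j] <- (a1[obs, j] == alt) + (a2[obs, j] == alt)
  }
  rownames(calls) <- ped[, 2]
  colnames(calls) <- map$snp_id
  genotype_matrix(calls, chromosome = map$chromosome,
                  position_bp = map$position_bp)
}

#' Write genotypes as a PLINK PED/MAP pair
#'
#' Emits alleles `A` (reference) and `B` (alternate, the counted allele);
#' missing calls become `0 0`. Fractional imputed dosages cannot be
#' represented and are an error.
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @export
write_genotypes_ped <- function(gm, ped_path,
                                map_path = sub("\\.ped$", ".map", ped_path)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  obs <- calls[!is.na(calls)]
  if (any(obs != round(obs)))
    stop("fractional dosages cannot be written as PED", call. = FALSE)
  write.table(data.frame(chromosome = gm$map$chromosome,
                         snp_id = gm$map$snp_id, cm = 0,
                         position_bp = gm$map$position_bp),
              map_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(calls)
  first <- matrix("A", n, ncol(calls))
  second <- matrix("A", n, ncol(calls))
  first[calls >= 1] <- "B"
  second[calls == 2] <- "B"
  first[is.na(calls)] <- "0"
  second[is.na(calls)] <- "0"
  geno <- matrix("", n, 2 * ncol(calls))
  geno[, seq(1, 2 * ncol(calls), 2)] <- first
  geno[, seq(2, 2 * ncol(calls), 2)] <- second
  out <- cbind(rownames(calls), rownames(calls), "0", "0", "0", "-9", geno)
  write.table(out, ped_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(ped_path)
}

#' Read/write genotypes in a simple TSV dialect
#'
#' Tab-separated table: first column `animal_id`, remaining columns one SNP
#' each holding 0/1/2 or `NA`. Chromosome/position metadata travel in a
#' companion `<path>.map.tsv` file (columns `snp_id`, `chromosome`,
#' `position_bp`).
#'
#' @param gm a [genotype_matrix()].
#' @param path TSV path.
#' @return `read_genotypes_tsv` returns a [genotype_matrix()].
#' @export
write_genotypes_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.frame(animal_id = rownames(gm$calls), gm$calls,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gm$map, paste0(path, ".map.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  map <- read.table(paste0(path, ".map.tsv"), sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$animal_id
  genotype_matrix(calls, chromosome = map$chromosome,
                  position_bp = map$position_bp)
}

#' Write simulation ground truth as TSV
#'
#' @param truth a `ground_truth` object.
#' @param snp_path,animal_path output paths for per-SNP effects/classes and
#'   per-animal breeding values.
#' @export
write_ground_truth <- function(truth, snp_path, animal_path) {
  stopifnot(inherits(truth, "ground_truth"))
  write.table(data.frame(effect = truth$true_snp_effects,
                         class = truth$true_component_assignments,
                         allele_freq = truth$allele_freq),
              snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(animal_id = names(truth$true_breeding_values),
                         true_bv = truth$true_breeding_values),
              animal_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(snp_path)
}
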