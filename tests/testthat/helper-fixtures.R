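# shared fixture builders; everything is generated in code

extdata <- function(name) {
  system.file("extdata", name, package = "smallgp", mustWork = TRUE)
}

# herd table with the worked-example composition: 1,260 herds, 1,896 cows
# (839x1, 297x2, 79x3, 21x4, 15x5, 5x6 and four large herds of 7, 8, 8, 14)
example_herdbook <- function() {
  sizes <- c(rep(1, 839), rep(2, 297), rep(3, 79), rep(4, 21),
             rep(5, 15), rep(6, 5), 7, 8, 8, 14)
  data.frame(
    animal_id = sprintf("A%04d", seq_len(sum(sizes))),
    herd_id = rep(sprintf("H%04d", seq_along(sizes)), sizes),
    stringsAsFactors = FALSE
  )
}

# small clean test-day table: n_cows cows x n_rec in-window records
toy_records <- function(n_cows = 6, n_rec = 4, fat = 4, seed = 1,
                        cdc = "CDC1") {
  set.seed(seed)
  data.frame(
    animal_id = rep(sprintf("C%02d", seq_len(n_cows)), each = n_rec),
    herd_id = rep(sprintf("H%02d", seq_len(n_cows)), each = n_rec),
    cdc_id = cdc,
    lactation_number = 1L,
    days_in_milk = rep(as.integer(round(seq(30, 300, length.out = n_rec))),
                       n_cows),
    year_month = "YM01",
    fat_pct = fat + rnorm(n_cows * n_rec, 0, 0.2),
    stringsAsFactors = FALSE
  )
}

# tiny genotype matrix; every SNP guaranteed polymorphic
toy_genotypes <- function(n = 6, m = 10, seed = 1) {
  set.seed(seed)
  calls <- matrix(rbinom(n * m, 2, 0.4), n, m,
                  dimnames = list(sprintf("C%02d", seq_len(n)),
                                  sprintf("S%02d", seq_len(m))))
  mono <- apply(calls, 2, function(x) length(unique(x)) == 1)
  calls[1, mono] <- ifelse(calls[1, mono] == 0, 1, calls[1, mono] - 1)
  genotype_matrix(calls, chromosome = rep_len(1:29, m))
}
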