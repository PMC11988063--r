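#' Quality-control ledger entries
#'
#' One audit row per filter: what was screened, what survived, what was
#' dropped, at which threshold. Conservation `retained + dropped = screened`
#' is enforced; if one of `retained`/`dropped` is missing it is derived.
#'
#' @param stage filter name.
#' @param threshold human-readable threshold description.
#' @param screened,retained,dropped entity counts.
#' @param unit what is counted ("record", "cow", "animal", "snp").
#' @return one-row data.frame of class `qc_ledger`.
#' @export
#' @examples
#' qc_ledger_entry("phenotypic QC", "all steps", 45978, retained = 33845)
qc_ledger_entry <- function(stage, threshold, screened, retained = NULL,
                            dropped = NULL, unit = "record") {
  if (is.null(retained) && is.null(dropped))
    stop("give at least one of retained/dropped", call. = FALSE)
  if (is.null(retained)) retained <- screened - dropped
  if (is.null(dropped)) dropped <- screened - retained
  if (retained + dropped != screened)
    stop("ledger conservation violated: retained + dropped != screened",
         call. = FALSE)
  structure(data.frame(stage = stage, unit = unit,
                       threshold = as.character(threshold),
                       screened = screened, retained = retained,
                       dropped = dropped, stringsAsFactors = FALSE),
            class = c("qc_ledger", "data.frame"))
}

bind_ledgers <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("qc_ledger", "data.frame")
  out
}

#' Write a QC ledger as tab-separated text
#' @param ledger a `qc_ledger` data.frame.
#' @param path output path.
#' @export
write_ledger <- function(ledger, path) {
  write.table(as.data.frame(ledger), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Step 1: retain cows with enough in-window test-day records
#'
#' Records outside the days-in-milk window are dropped first; then every
#' (cow, lactation) group left with fewer than `min_records` records is
#' dropped entirely. The ledger counts records.
#'
#' @param records test-day record data.frame (columns `animal_id`,
#'   `lactation_number`, `days_in_milk`, `fat_pct`, ...).
#' @param min_records minimum records per cow per lactation (default 4).
#' @param dim_window closed DIM window, default `c(8, 340)`.
#' @return list with filtered `records` and a `ledger` row.
#' @export
filter_min_records <- function(records, min_records = 4L,
                               dim_window = c(8, 340)) {
  if (nrow(records) == 0L) stop("empty phenotype input", call. = FALSE)
  n0 <- nrow(records)
  inwin <- records$days_in_milk >= dim_window[1] &
    records$days_in_milk <= dim_window[2]
  rec <- records[inwin, , drop = FALSE]
  grp <- interaction(rec$animal_id, rec$lactation_number, drop = TRUE)
  counts <- table(grp)
  keep <- grp %in% names(counts)[counts >= min_records]
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec,
       ledger = qc_ledger_entry(
         "min records per lactation",
         sprintf(">=%d records, DIM [%g,%g]", min_records,
                 dim_window[1], dim_window[2]),
         screened = n0, retained = nrow(rec)))
}

#' Step 2: remove cows with an outlying mean fat percentage
#'
#' Computes each cow's mean fat percentage, then the population mean and SD
#' over cow means, and removes (with all their records) cows whose mean is
#' strictly greater than `mean + k_sd * SD`. One-sided above by default;
#' `two_sided = TRUE` also removes cows below `mean - k_sd * SD`.
#'
#' @param records test-day record data.frame.
#' @param k_sd SD multiplier (default 3).
#' @param two_sided also filter the lower tail.
#' @return list with filtered `records` and a `ledger` row.
#' @export
filter_outlier_cows <- function(records, k_sd = 3, two_sided = FALSE) {
  if (length(unique(records$animal_id)) < 2L)
    stop("need at least 2 distinct cows", call. = FALSE)
  n0 <- nrow(records)
  mu_cow <- tapply(records$fat_pct, records$animal_id, mean)
  m <- mean(mu_cow); s <- sd(mu_cow)
  if (s == 0 && k_sd > 0) {
    warning("zero SD across cow means; no cows removed")
    bad <- character(0)
  } else {
    out <- mu_cow > m + k_sd * s
    if (two_sided) out <- out | (mu_cow < m - k_sd * s)
    bad <- names(mu_cow)[out]
  }
  rec <- records[!(records$animal_id %in% bad), , drop = FALSE]
  rownames(rec) <- NULL
  out <- list(records = rec,
              ledger = qc_ledger_entry(
                "outlier cow means",
                sprintf("mean > pop mean + %g SD%s", k_sd,
                        if (two_sided) " (two-sided)" else ""),
                screened = n0, retained = nrow(rec)))
  out$removed_cows <- bad
  out
}

#' Step 3: remove records with outlying standardized residuals
#'
#' Fits an ordinary least-squares regression of fat percentage on the
#' stage-1 fixed effects (lactation number, CDC, year-month-by-CDC) and
#' removes records whose internally studentized residual falls strictly
#' outside the closed `residual_limits` band.
#'
#' @param records test-day record data.frame with complete factor columns.
#' @param residual_limits closed band, default `c(-2, 2)`.
#' @param include_dim add Legendre DIM covariates of this order to the
#'   regression (`NULL`, the default, excludes days in milk).
#' @return list with filtered `records`, a `ledger` row, and the fitted
#'   standardized residuals (`std_residuals`).
#' @export
filter_residual_outliers <- function(records, residual_limits = c(-2, 2),
                                     include_dim = NULL) {
  need <- c("lactation_number", "cdc_id", "year_month", "fat_pct")
  if (!all(need %in% names(records)))
    stop("records must carry fixed-effect columns: ",
         paste(setdiff(need, names(records)), collapse = ", "), call. = FALSE)
  n0 <- nrow(records)
  df <- data.frame(y = records$fat_pct,
                   lact = factor(records$lactation_number),
                   cdc = factor(records$cdc_id),
                   ym = factor(records$year_month))
  terms <- c(if (nlevels(df$lact) > 1L) "lact",
             if (nlevels(df$cdc) > 1L) "cdc",
             if (nlevels(df$ym) > 1L) {
               if (nlevels(df$cdc) > 1L) "ym:cdc" else "ym"
             })
  if (!is.null(include_dim)) {
    phi <- legendre_covariates(records$days_in_milk, include_dim)
    df <- cbind(df, as.data.frame(phi[, -1, drop = FALSE]))
    terms <- c(terms, colnames(phi)[-1])
  }
  form <- if (length(terms))
    stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  else y ~ 1
  fit <- lm(form, data = df)  # aliased interaction cells dropped by lm
  s2_fit <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  if (s2_fit < 1e-12 * (mean(df$y^2) + 1e-300)) {
    r <- rep(0, nrow(df))  # numerically perfect fit: nothing to flag
  } else {
    r <- rstandard(fit)
    r[!is.finite(r)] <- 0  # unit-leverage records cannot be judged
  }
  keep <- r >= residual_limits[1] & r <= residual_limits[2]
  rec <- records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec,
       ledger = qc_ledger_entry(
         "standardized residual band",
         sprintf("within [%g, %g]", residual_limits[1], residual_limits[2]),
         screened = n0, retained = nrow(rec)),
       std_residuals = r)
}

#' Run the three sequential phenotypic QC steps
#'
#' Steps run strictly in order: (1) DIM window and minimum records per
#' lactation, (2) cow-mean outlier removal, (3) standardized-residual
#' record removal. Step 2 statistics are computed on the step-1 survivors.
#'
#' @inheritParams filter_min_records
#' @inheritParams filter_outlier_cows
#' @inheritParams filter_residual_outliers
#' @return list with final `records` and the cumulative three-row `ledger`.
#' @export
run_pheno_qc <- function(records, min_records = 4L, dim_window = c(8, 340),
                         k_sd = 3, residual_limits = c(-2, 2),
                         two_sided = FALSE, include_dim = NULL) {
  s1 <- filter_min_records(records, min_records, dim_window)
  s2 <- filter_outlier_cows(s1$records, k_sd, two_sided)
  s3 <- filter_residual_outliers(s2$records, residual_limits, include_dim)
  list(records = s3$records,
       ledger = bind_ledgers(s1$ledger, s2$ledger, s3$ledger),
       removed_cows = s2$removed_cows)
}

#' Herd-size composition report
#'
#' Buckets herds by their number of distinct cows, with an open-ended top
#' bucket ("7 and above" by default), and appends a totals row. Reports the
#' share of herds and the share of animals in each bucket.
#'
#' @param records data.frame with `animal_id` and `herd_id` columns (any
#'   table with one or more rows per cow works; cows are counted distinct).
#' @param top_bucket smallest size pooled into the open-ended bucket.
#' @return data.frame with columns `herd_size`, `n_herds`, `n_animals`,
#'   `pct_herds`, `pct_animals`; last row is the total.
#' @export
herd_composition <- function(records, top_bucket = 7L) {
  stopifnot(all(c("animal_id", "herd_id") %in% names(records)))
  sizes <- tapply(records$animal_id, records$herd_id,
                  function(a) length(unique(a)))
  bucket <- ifelse(sizes >= top_bucket, paste0(top_bucket, " and above"),
                   as.character(sizes))
  lev <- c(as.character(seq_len(top_bucket - 1L)),
           paste0(top_bucket, " and above"))
  bucket <- factor(bucket, levels = lev)
  n_herds <- tapply(rep(1L, length(sizes)), bucket, sum)
  n_animals <- tapply(sizes, bucket, sum)
  n_herds[is.na(n_herds)] <- 0L
  n_animals[is.na(n_animals)] <- 0L
  out <- data.frame(herd_size = lev,
                    n_herds = as.integer(n_herds),
                    n_animals = as.integer(n_animals),
                    stringsAsFactors = FALSE)
  out <- out[out$n_herds > 0, , drop = FALSE]
  tot <- data.frame(herd_size = "Total", n_herds = sum(out$n_herds),
                    n_animals = sum(out$n_animals))
  out$pct_herds <- 100 * out$n_herds / tot$n_herds
  out$pct_animals <- 100 * out$n_animals / tot$n_animals
  tot$pct_herds <- 100; tot$pct_animals <- 100
  rbind(out, tot)
}

#' Histogram of fat percentage before and after QC
#'
#' @param before,after record data.frames with `fat_pct`.
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the two hist objects.
#' @export
plot_fat_histograms <- function(before, after, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h1 <- graphics::hist(before$fat_pct, main = "Before QC",
                       xlab = "Fat %", ...)
  h2 <- graphics::hist(after$fat_pct, main = "After QC", xlab = "Fat %", ...)
  invisible(list(before = h1, after = h2))
}
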