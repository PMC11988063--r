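#' Build the stage-1 repeatability-model design
#'
#' Assembles `y = X b + Z1 a + Z2 h + e`: fixed effects are lactation
#' number, CDC, and the year-month-by-CDC interaction (treatment coding,
#' reference level absorbed into the intercept); `Z1`/`Z2` are sparse
#' incidence matrices for animal and herd. Columns of `X` made redundant by
#' confounded interaction cells are dropped by a rank-revealing QR so the
#' fixed-effect block is full rank.
#'
#' @param records test-day record data.frame with complete columns
#'   `animal_id`, `herd_id`, `cdc_id`, `lactation_number`, `year_month`,
#'   `fat_pct`.
#' @return object of class `stage1_design`: list with `y`, `X` (dense),
#'   `Z1`, `Z2` (sparse), `animal_ids`, `herd_ids`, `records`.
#' @export
build_design <- function(records) {
  need <- c("animal_id", "herd_id", "cdc_id", "lactation_number",
            "year_month", "fat_pct")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !complete.cases(records[need])
  if (any(bad))
    stop("record(s) with missing factor levels or values: rows ",
         paste(head(which(bad)), collapse = ", "), call. = FALSE)
  df <- data.frame(lact = factor(records$lactation_number),
                   cdc = factor(records$cdc_id),
                   ym = factor(records$year_month))
  # single-level factors carry no contrast: collapse the affected terms
  terms <- c(if (nlevels(df$lact) > 1L) "lact",
             if (nlevels(df$cdc) > 1L) "cdc",
             if (nlevels(df$ym) > 1L) {
               if (nlevels(df$cdc) > 1L) "ym:cdc" else "ym"
             })
  form <- if (length(terms))
    stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  else ~ 1
  X <- model.matrix(form, df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  animal_ids <- sort(unique(records$animal_id))
  herd_ids <- sort(unique(records$herd_id))
  Z1 <- sparseMatrix(i = seq_len(nrow(records)),
                     j = match(records$animal_id, animal_ids),
                     x = 1, dims = c(nrow(records), length(animal_ids)))
  Z2 <- sparseMatrix(i = seq_len(nrow(records)),
                     j = match(records$herd_id, herd_ids),
                     x = 1, dims = c(nrow(records), length(herd_ids)))
  structure(list(y = records$fat_pct, X = X, Z1 = Z1, Z2 = Z2,
                 animal_ids = animal_ids, herd_ids = herd_ids,
                 records = records),
            class = "stage1_design")
}

# assemble Henderson's MME coefficient matrix and RHS for given ratios
mme_system <- function(design, lambda_a, lambda_h) {
  X <- design$X; Z1 <- as.matrix(design$Z1); Z2 <- as.matrix(design$Z2)
  W <- cbind(X, Z1, Z2)
  C <- crossprod(W)
  p <- ncol(X); qa <- ncol(Z1); qh <- ncol(Z2)
  ia <- p + seq_len(qa); ih <- p + qa + seq_len(qh)
  diag(C)[ia] <- diag(C)[ia] + lambda_a
  diag(C)[ih] <- diag(C)[ih] + lambda_h
  list(C = as.matrix(C), rhs = drop(crossprod(W, design$y)),
       p = p, ia = ia, ih = ih)
}

#' Estimate stage-1 variance components by EM-REML
#'
#' EM-REML on Henderson's mixed-model equations for the repeatability
#' model with identity covariances for animal and herd effects (animals
#' treated as unrelated at this stage). Iterates until the largest absolute
#' change across the three components falls below `tolerance`. Components
#' shrinking to the zero boundary are clamped at a small floor and no longer
#' counted against convergence.
#'
#' @param design a [build_design()] result; needs repeated records for at
#'   least some animals to separate animal from residual variance.
#' @param init optional named list of starting values
#'   (`sigma2_a`, `sigma2_h`, `sigma2_e`).
#' @param fix optional named list of components to hold fixed (not
#'   updated), e.g. `list(sigma2_h = 1e-10)` to pin an unidentified herd
#'   variance.
#' @param tolerance convergence tolerance on component changes (fat%^2).
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   trajectory in its `condition` data.
#' @return named list `sigma2_a`, `sigma2_h`, `sigma2_e` with attribute
#'   `"trajectory"` (iteration history).
#' @export
estimate_variances_em_reml <- function(design, init = NULL, fix = list(),
                                       tolerance = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(design, "stage1_design"))
  reps <- table(design$records$animal_id)
  if (sum(reps >= 2L) < 2L)
    stop("need at least 2 animals with repeated records", call. = FALSE)
  y <- design$y
  vy <- var(y)
  floor_v <- 1e-8 * vy
  s2a <- fix$sigma2_a %||% init$sigma2_a %||% (0.2 * vy)
  s2h <- fix$sigma2_h %||% init$sigma2_h %||% (0.1 * vy)
  s2e <- fix$sigma2_e %||% init$sigma2_e %||% (0.7 * vy)
  n <- length(y)
  traj <- matrix(NA_real_, max_iter, 3,
                 dimnames = list(NULL, c("sigma2_a", "sigma2_h", "sigma2_e")))
  for (it in seq_len(max_iter)) {
    sys <- mme_system(design, s2e / s2a, s2e / s2h)
    ch <- chol(sys$C)
    sol <- backsolve(ch, forwardsolve(t(ch), sys$rhs))
    Cinv <- chol2inv(ch)
    a <- sol[sys$ia]; h <- sol[sys$ih]
    qa <- length(sys$ia); qh <- length(sys$ih)
    s2a_new <- fix$sigma2_a %||%
      max((sum(a^2) + s2e * sum(diag(Cinv)[sys$ia])) / qa, floor_v)
    s2h_new <- fix$sigma2_h %||%
      max((sum(h^2) + s2e * sum(diag(Cinv)[sys$ih])) / qh, floor_v)
    s2e_new <- fix$sigma2_e %||%
      max((sum(y^2) - sum(sol * sys$rhs)) / (n - sys$p), floor_v)
    delta <- c(if (is.null(fix$sigma2_a) &&
                     (s2a > floor_v || s2a_new > floor_v)) abs(s2a_new - s2a),
               if (is.null(fix$sigma2_h) &&
                     (s2h > floor_v || s2h_new > floor_v)) abs(s2h_new - s2h),
               if (is.null(fix$sigma2_e)) abs(s2e_new - s2e))
    s2a <- s2a_new; s2h <- s2h_new; s2e <- s2e_new
    traj[it, ] <- c(s2a, s2h, s2e)
    if (max(delta) < tolerance) {
      out <- list(sigma2_a = s2a, sigma2_h = s2h, sigma2_e = s2e)
      attr(out, "trajectory") <- traj[seq_len(it), , drop = FALSE]
      attr(out, "iterations") <- it
      return(out)
    }
  }
  cond <- simpleError(sprintf(
    "EM-REML did not converge in %d iterations (last delta %.3g)",
    max_iter, max(delta)))
  cond$trajectory <- traj
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve Henderson's mixed-model equations for the stage-1 model
#'
#' BLUE of fixed effects and BLUP of animal and herd effects under identity
#' covariance structures (animals assumed unrelated at this stage), at the
#' given variance components.
#'
#' @param design a [build_design()] result.
#' @param varcomp named list `sigma2_a`, `sigma2_h`, `sigma2_e`
#'   (`sigma2_e > 0`).
#' @return object of class `stage1_fit`: `b_hat`, `a_hat` (named by
#'   animal), `h_hat` (named by herd), `e_hat`, `fitted`, `varcomp`,
#'   `design`.
#' @export
solve_mme <- function(design, varcomp) {
  stopifnot(inherits(design, "stage1_design"))
  if (!(varcomp$sigma2_e > 0))
    stop("sigma2_e must be positive", call. = FALSE)
  lam_a <- varcomp$sigma2_e / max(varcomp$sigma2_a, 1e-12)
  lam_h <- varcomp$sigma2_e / max(varcomp$sigma2_h, 1e-12)
  sys <- mme_system(design, lam_a, lam_h)
  ch <- tryCatch(chol(sys$C), error = function(e)
    stop("singular mixed-model equations; merge confounded fixed-effect ",
         "levels", call. = FALSE))
  sol <- backsolve(ch, forwardsolve(t(ch), sys$rhs))
  b <- sol[seq_len(sys$p)]
  a <- setNames(sol[sys$ia], design$animal_ids)
  h <- setNames(sol[sys$ih], design$herd_ids)
  fitted <- unname(drop(design$X %*% b) +
                     drop(as.matrix(design$Z1 %*% a)) +
                     drop(as.matrix(design$Z2 %*% h)))
  structure(list(b_hat = setNames(b, colnames(design$X)[seq_len(sys$p)]),
                 a_hat = a, h_hat = h,
                 e_hat = design$y - fitted, fitted = fitted,
                 varcomp = varcomp, design = design),
            class = "stage1_fit")
}

#' Adjusted test-day records from a stage-1 fit
#'
#' Per record: `ife` (the record-level residual after removing estimated
#' fixed effects and BLUPs), `are` (the animal BLUP), `hre` (the herd
#' BLUP), and the adjusted fat percentage `afp = ife + are + hre`, which
#' equals `y - X b_hat`. The adjusted record is the stage-2 response.
#'
#' @param fit a [solve_mme()] result.
#' @param records optional record table (defaults to the fit's own); must
#'   only contain animals/herds present in the fit.
#' @return data.frame with `animal_id`, `herd_id`, `days_in_milk`,
#'   `lactation_number`, `ife`, `are`, `hre`, `afp`.
#' @export
adjust_records <- function(fit, records = NULL) {
  stopifnot(inherits(fit, "stage1_fit"))
  if (is.null(records)) {
    records <- fit$design$records
    ife <- fit$e_hat
  } else {
    if (!all(records$animal_id %in% names(fit$a_hat)) ||
        !all(records$herd_id %in% names(fit$h_hat)))
      stop("records contain animals/herds without stage-1 solutions",
           call. = FALSE)
    stop("adjusting external records requires the design rows they were ",
         "fit with; pass records = NULL", call. = FALSE)
  }
  are <- unname(fit$a_hat[records$animal_id])
  hre <- unname(fit$h_hat[records$herd_id])
  data.frame(animal_id = records$animal_id,
             herd_id = records$herd_id,
             days_in_milk = records$days_in_milk,
             lactation_number = records$lactation_number,
             ife = ife, are = are, hre = hre,
             afp = ife + are + hre,
             stringsAsFactors = FALSE)
}

#' Compose adjusted fat percentage from its components
#'
#' Utility over a component table (columns `ife`, `are`, `hre`): the
#' adjusted record is their exact sum. Published tables may differ by
#' +/- 0.01 from this sum through rounding of the printed components.
#'
#' @param components data.frame with numeric `ife`, `are`, `hre`.
#' @return the same data.frame with an `afp` column appended/overwritten.
#' @export
#' @examples
#' compose_adjusted_records(data.frame(ife = 0.44, are = 0.30, hre = 0.05))
compose_adjusted_records <- function(components) {
  stopifnot(all(c("ife", "are", "hre") %in% names(components)))
  components$afp <- components$ife + components$are + components$hre
  components
}

#' Write adjusted records as CSV
#' @param adjusted data.frame from [adjust_records()].
#' @param path output path.
#' @export
write_adjusted_records <- function(adjusted, path) {
  out <- data.frame(AnimalID = adjusted$animal_id,
                    IFE = adjusted$ife, ARE = adjusted$are,
                    HRE = adjusted$hre, AFP = adjusted$afp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
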