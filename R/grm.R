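#' VanRaden genomic relationship matrix
#'
#' Method-1 construction: centered genotype dosages `W = M - 2P` and
#' `G = W W' / (2 * sum p_j (1 - p_j))`, with allele frequencies computed
#' from the data unless supplied. Missing calls are mean-imputed before
#' centering (QC caps missingness, so the impact is small). With
#' `method = 2` each SNP is standardized by `sqrt(2 p q)` and `G = W W'/m`.
#'
#' @param gm a QC-passed [genotype_matrix()]; monomorphic SNPs are an error
#'   (the MAF filter should have removed them).
#' @param allele_freqs optional per-SNP frequencies used for centering.
#' @param method 1 (default) or 2.
#' @return object of class `grm`: list with `values` (symmetric matrix,
#'   animal ids as dimnames), `allele_freqs`, `method`.
#' @export
#' @examples
#' gm <- simulate_genotypes(sim_config(n_snps = 500, seed = 3), n_animals = 20)
#' G <- vanraden_grm(gm)
#' mean(diag(G$values))  # ~1
vanraden_grm <- function(gm, allele_freqs = NULL, method = 1L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  M <- mean_imputer(gm)$calls
  p <- if (is.null(allele_freqs)) colMeans(M) / 2 else allele_freqs
  if (length(p) != ncol(M))
    stop("allele_freqs must have one entry per SNP", call. = FALSE)
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop("monomorphic SNP(s) present (run QC first): ",
         paste(head(colnames(M)[mono]), collapse = ", "), call. = FALSE)
  W <- sweep(M, 2L, 2 * p)
  if (method == 1L) {
    G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  } else if (method == 2L) {
    W <- sweep(W, 2L, sqrt(2 * p * (1 - p)), "/")
    G <- tcrossprod(W) / ncol(W)
  } else stop("method must be 1 or 2", call. = FALSE)
  G <- (G + t(G)) / 2
  structure(list(values = G, allele_freqs = p, method = method),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("grm:", nrow(x$values), "animals (VanRaden method", x$method, ")\n")
  cat(sprintf("  mean diagonal %.3f, mean off-diagonal %.4f\n",
              mean(diag(x$values)),
              mean(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Blend a genomic relationship matrix towards the identity
#'
#' `G* = (1 - w) G + w I` guarantees an invertible, positive-definite
#' relationship matrix for the mixed-model equations and the Gibbs sampler
#' (a Gram-matrix G is only positive semi-definite, and duplicate or cloned
#' genotypes make it singular).
#'
#' @param G a `grm` (or bare symmetric matrix).
#' @param blend_weight `w` in `[0, 1)`, default 0.01.
#' @return same type as `G`, blended; errors if the result is still not
#'   positive definite (reporting the smallest eigenvalue).
#' @export
stabilize_grm <- function(G, blend_weight = 0.01) {
  if (blend_weight < 0 || blend_weight >= 1)
    stop("blend_weight must lie in [0, 1)", call. = FALSE)
  vals <- if (inherits(G, "grm")) G$values else G
  out <- (1 - blend_weight) * vals + blend_weight * diag(nrow(vals))
  ev_min <- min(eigen(out, symmetric = TRUE, only.values = TRUE)$values)
  # a data-frequency GRM is always singular (centered W has rank <= n-1),
  # so "positive definite" here means numerically invertible
  if (ev_min <= 1e-10)
    stop(sprintf(
      "blended matrix still not positive definite (min eigenvalue %.3e)",
      ev_min), call. = FALSE)
  if (inherits(G, "grm")) {
    G$values <- out
    G$blend_weight <- blend_weight
    G
  } else out
}

#' Write a genomic relationship matrix as tab-separated text
#'
#' Writes the full symmetric matrix with animal ids, plus (optionally) a
#' long-format triplet file `i  j  value` with a separate id index.
#'
#' @param G a `grm`.
#' @param path output path for the full matrix TSV.
#' @param triplet_path optional path for the triplet form (lower triangle).
#' @export
write_grm <- function(G, path, triplet_path = NULL) {
  stopifnot(inherits(G, "grm"))
  write.table(G$values, path, sep = "\t", quote = FALSE,
              col.names = NA)
  if (!is.null(triplet_path)) {
    idx <- which(lower.tri(G$values, diag = TRUE), arr.ind = TRUE)
    trip <- data.frame(i = idx[, 1], j = idx[, 2],
                       value = G$values[idx])
    write.table(trip, triplet_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(index = seq_len(nrow(G$values)),
                           animal_id = rownames(G$values)),
                paste0(triplet_path, ".ids"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
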