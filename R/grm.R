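#' Genomic relationship matrix
#'
#' GCTA-style standardized cross-product: for samples j, k,
#' `A_jk = (1/M_jk) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`
#' over the biallelic sites with panel-wide frequency `0 < p_i < 1` at
#' which both calls are non-missing (`M_jk` is counted per pair, so
#' missingness is tolerated without imputation). Swapping REF/ALT labels
#' at any site leaves the matrix unchanged.
#'
#' @param gm a [geno_matrix()].
#' @return A `grm_matrix` list: `values` (symmetric samples x samples),
#'   `sample_ids`, `n_sites_used`, `M` (per-pair site counts).
#' @export
grm <- function(gm) {
  X <- dosage(gm)
  p <- rowMeans(X, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1 & n_alt_alleles(gm) == 1L
  if (!any(use)) stop("no usable (polymorphic biallelic) sites for GRM")
  X <- X[use, , drop = FALSE]
  p <- p[use]
  Z <- (X - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(Z)
  Z[!obs] <- 0
  M <- crossprod(obs)
  A <- crossprod(Z) / M
  dimnames(A) <- list(gm$sample_ids, gm$sample_ids)
  structure(list(values = A, sample_ids = gm$sample_ids,
                 n_sites_used = sum(use), M = M),
            class = "grm_matrix")
}

#' Principal components of a relationship matrix
#'
#' Eigen-decomposition of the double-centered relationship matrix.
#' Coordinates are `eigenvector * sqrt(eigenvalue)`; the variance fraction
#' of each component is its eigenvalue over the sum of positive
#' eigenvalues. Sign convention: the largest-magnitude loading of each
#' component is positive, fixing the output for reproducibility.
#'
#' @param rm a `grm_matrix` from [grm()].
#' @param k number of components, `k < n_samples`.
#' @return List: `coords` (data frame sample, PC1..PCk), `var_frac`,
#'   `eigenvalues` (all), `residual` (max `||C v - lambda v||` over the
#'   reported pairs, on the centered matrix `C`).
#' @export
pca_grm <- function(rm, k = 2) {
  A <- rm$values
  if (any(!is.finite(A))) stop("relationship matrix has non-finite entries")
  n <- nrow(A)
  stopifnot(k >= 1, k < n)
  rc <- rowMeans(A); cc <- colMeans(A); gc <- mean(A)
  C <- A - outer(rc, rep(1, n)) - outer(rep(1, n), cc) + gc
  C <- (C + t(C)) / 2
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values[seq_len(k)]
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    m <- which.max(abs(vecs[, i]))
    if (vecs[m, i] < 0) vecs[, i] <- -vecs[, i]
  }
  coords <- sweep(vecs, 2L, sqrt(pmax(vals, 0)), `*`)
  colnames(coords) <- paste0("PC", seq_len(k))
  resid <- max(vapply(seq_len(k), function(i)
    sqrt(sum((C %*% vecs[, i] - vals[i] * vecs[, i])^2)), numeric(1)))
  pos <- sum(e$values[e$values > 0])
  list(coords = data.frame(sample = rm$sample_ids, coords,
                           stringsAsFactors = FALSE),
       var_frac = vals / pos, eigenvalues = e$values, residual = resid)
}
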