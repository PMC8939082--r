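#' Pairwise linkage disequilibrium r-squared for two sites
#'
#' Haplotype mode uses phased alleles: `D = p_AB - p_A p_B` and
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`. Dosage mode (unphased-safe)
#' is the squared Pearson correlation of alt-allele dosages over
#' pairwise-complete samples. Both are invariant to swapping REF/ALT
#' labels.
#'
#' @param gm a [geno_matrix()].
#' @param i,j site indices.
#' @param samples optional sample subset (names or indices).
#' @param mode `"dosage"` or `"haplotype"`.
#' @return List with `r2` (NA when either site is monomorphic among the
#'   informative samples), `n` (samples/haplotypes used) and, in haplotype
#'   mode, `D`, `p_a`, `p_b`.
#' @export
pair_r2 <- function(gm, i, j, samples = NULL, mode = c("dosage", "haplotype")) {
  mode <- match.arg(mode)
  if (is.null(samples)) samples <- gm$sample_ids
  sub <- gm_subset(gm, sites = c(i, j), samples = samples)
  if (mode == "haplotype") {
    x <- c(sub$a1[1L, ], sub$a2[1L, ])
    y <- c(sub$a1[2L, ], sub$a2[2L, ])
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    pa <- mean(x); pb <- mean(y)
    if (length(x) < 2L || pa %in% c(0, 1) || pb %in% c(0, 1))
      return(list(r2 = NA_real_, n = length(x)))
    D <- mean(x * y) - pa * pb
    list(r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)),
         D = D, p_a = pa, p_b = pb, n = length(x))
  } else {
    d <- dosage(sub)
    ok <- !is.na(d[1L, ]) & !is.na(d[2L, ])
    x <- d[1L, ok]; y <- d[2L, ok]
    if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(r2 = NA_real_, n = length(x)))
    list(r2 = stats::cor(x, y)^2, n = length(x))
  }
}

# vectorized r2 over index pairs (ii, jj) of a numeric data matrix
# (rows = sites): squared pairwise-complete Pearson correlation.
# Works on dosages or on a haplotype matrix alike.
r2_pairs <- function(X, ii, jj) {
  A <- X[ii, , drop = FALSE]; B <- X[jj, , drop = FALSE]
  M <- !is.na(A) & !is.na(B)
  A[!M] <- 0; B[!M] <- 0
  n <- rowSums(M)
  sa <- rowSums(A); sb <- rowSums(B)
  saa <- rowSums(A * A); sbb <- rowSums(B * B); sab <- rowSums(A * B)
  va <- n * saa - sa^2; vb <- n * sbb - sb^2
  num <- (n * sab - sa * sb)^2
  out <- ifelse(n >= 2 & va > 0 & vb > 0, num / (va * vb), NA_real_)
  out
}

#' Binned LD decay
#'
#' Same-chromosome SNP pairs are assigned to right-closed physical-distance
#' bins `(d_low, d_high]`; bins exceeding `max_pairs_per_bin` candidate
#' pairs are subsampled with a seeded uniform draw. Pairs with a
#' monomorphic member are skipped and counted. Default bin edges follow the
#' conventional 1, 3, 5, 15, 60, 100 kb distances.
#'
#' @param gm a [geno_matrix()].
#' @param pm optional `pop_map`; with `group`, restricts to that
#'   group/superset's samples.
#' @param group optional group or superset label.
#' @param bin_edges_kb ascending bin edges in kb (first edge exclusive).
#' @param mode `"dosage"` or `"haplotype"` (phased alleles).
#' @param max_pairs_per_bin cap on evaluated pairs per bin.
#' @param seed seed for the subsampling draw.
#' @return Data frame (d_low_kb, d_high_kb, n_pairs, mean_r2,
#'   n_monomorphic_skipped).
#' @export
ld_decay <- function(gm, pm = NULL, group = NULL,
                     bin_edges_kb = c(0, 1, 3, 5, 15, 60, 100),
                     mode = c("dosage", "haplotype"),
                     max_pairs_per_bin = 10000, seed = 1) {
  mode <- match.arg(mode)
  samples <- if (!is.null(group)) resolve_samples(pm, group) else gm$sample_ids
  if (length(samples) < 2L) stop("need at least 2 samples for LD decay")
  sub <- gm_subset(gm, samples = samples)
  X <- if (mode == "dosage") dosage(sub) else cbind(sub$a1, sub$a2)
  edges <- bin_edges_kb * 1000
  nb <- length(edges) - 1L
  max_d <- edges[length(edges)]
  ii <- jj <- integer(0)
  for (ch in unique(sub$chrom)) {
    sidx <- which(sub$chrom == ch)
    p <- sub$pos[sidx]
    last <- findInterval(p + max_d, p)
    reps <- pmax(last - seq_along(p), 0L)
    a <- rep(seq_along(p), reps)
    b <- unlist(lapply(which(reps > 0L), function(k) (k + 1L):last[k]),
                use.names = FALSE)
    ii <- c(ii, sidx[a]); jj <- c(jj, sidx[b])
  }
  d <- sub$pos[jj] - sub$pos[ii]
  bin <- findInterval(d - 0.5, edges)   # right-closed bins on integer bp
  keep <- bin >= 1L & bin <= nb & d > edges[1]
  ii <- ii[keep]; jj <- jj[keep]; bin <- bin[keep]
  set.seed(seed)
  out <- data.frame(d_low_kb = bin_edges_kb[-length(bin_edges_kb)],
                    d_high_kb = bin_edges_kb[-1L],
                    n_pairs = 0L, mean_r2 = NA_real_,
                    n_monomorphic_skipped = 0L)
  for (b in seq_len(nb)) {
    sel <- which(bin == b)
    if (length(sel) > max_pairs_per_bin)
      sel <- sort(sample(sel, max_pairs_per_bin))
    if (!length(sel)) next
    r2 <- r2_pairs(X, ii[sel], jj[sel])
    out$n_pairs[b] <- sum(!is.na(r2))
    out$n_monomorphic_skipped[b] <- sum(is.na(r2))
    out$mean_r2[b] <- mean(r2, na.rm = TRUE)
  }
  out
}

#' Greedy windowed LD pruning
#'
#' Sliding windows of `window_snps` SNPs advance by `step_snps`; within a
#' window, while any surviving pair has `r2 > r2_max`, the member of the
#' worst (highest-r2) pair with the lower minor-allele frequency is removed
#' (ties remove the later position). Passes repeat until no window contains
#' an offending pair, so the post-condition holds under re-scan. Defaults
#' mirror the common 50 / 10 / 0.1 pruning convention.
#'
#' @param gm a [geno_matrix()].
#' @param samples optional sample subset used to compute r2 and MAF;
#'   default all samples.
#' @param window_snps,step_snps window and step in SNP counts.
#' @param r2_max maximum tolerated pairwise dosage r2.
#' @return List: `keep` (surviving site indices), `removed`, `n_passes`.
#' @export
ld_prune <- function(gm, samples = NULL, window_snps = 50, step_snps = 10,
                     r2_max = 0.1) {
  if (is.null(samples)) samples <- gm$sample_ids
  D <- dosage(gm)[, samples, drop = FALSE]
  p <- rowMeans(D, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, n_sites(gm))
  n_passes <- 0L
  repeat {
    n_passes <- n_passes + 1L
    removed_any <- FALSE
    for (ch in unique(gm$chrom)) {
      idx <- which(keep & gm$chrom == ch)
      if (length(idx) < 2L) next
      st <- 1L
      while (st <= length(idx)) {
        w <- idx[st:min(st + window_snps - 1L, length(idx))]
        w <- w[keep[w]]   # drop removals from earlier windows of this pass
        if (length(w) >= 2L) {
          R2 <- suppressWarnings(
            stats::cor(t(D[w, , drop = FALSE]),
                       use = "pairwise.complete.obs")^2)
          R2[!is.finite(R2)] <- 0
          diag(R2) <- 0
          while (max(R2) > r2_max) {
            worst <- which(R2 == max(R2), arr.ind = TRUE)[1L, ]
            s1 <- w[worst[1L]]; s2 <- w[worst[2L]]
            drop_site <- if (maf[s1] < maf[s2]) s1
                         else if (maf[s2] < maf[s1]) s2
                         else max(s1, s2)         # tie: later position
            keep[drop_site] <- FALSE
            removed_any <- TRUE
            k <- match(drop_site, w)
            R2[k, ] <- 0; R2[, k] <- 0
          }
        }
        st <- st + step_snps
      }
    }
    if (!removed_any) break
  }
  list(keep = which(keep), removed = which(!keep), n_passes = n_passes)
}
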