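# Per-group genotype counts at every site: list of matrices keyed by what
# downstream statistics need. `samples` selects the group's columns.
group_site_counts <- function(gm, samples) {
  unknown <- setdiff(samples, gm$sample_ids)
  if (length(unknown))
    stop("unknown sample: ", paste(unknown, collapse = ", "))
  d <- dosage(gm)[, samples, drop = FALSE]
  n <- rowSums(!is.na(d))                 # non-missing diploids
  het <- rowSums(d == 1L, na.rm = TRUE)
  alt <- rowSums(d, na.rm = TRUE)         # alt allele count
  list(n_dip = n, n_allele = 2L * n, het = het,
       c_alt = alt, c_ref = 2L * n - alt,
       p = ifelse(n > 0L, alt / (2 * n), NA_real_),
       h = ifelse(n > 0L, het / n, NA_real_))
}

#' Per-group heterozygosity and polymorphism summary
#'
#' For each group: mean observed heterozygosity Ho (fraction of
#' heterozygous calls per site, averaged over sites with at least one
#' non-missing call), mean expected heterozygosity He (plug-in
#' `2 p (1 - p)` from the within-group allele frequency), and Pn, the
#' proportion of SNPs polymorphic within the group.
#'
#' @param gm a filtered [geno_matrix()].
#' @param pm a `pop_map`.
#' @param he_correction apply the small-sample factor `n/(n-1)` (allele
#'   count based) to He; off by default, matching the plug-in convention.
#' @return Data frame (group, n_samples, n_sites, Ho, He, Pn).
#' @export
het_summary <- function(gm, pm, he_correction = FALSE) {
  groups <- unique(pm$group)
  out <- lapply(groups, function(g) {
    samp <- pm$sample[pm$group == g]
    if (!length(samp)) stop("group has zero samples: ", g)
    cs <- group_site_counts(gm, samp)
    use <- cs$n_dip > 0L
    he <- 2 * cs$p[use] * (1 - cs$p[use])
    if (he_correction) {
      na <- cs$n_allele[use]
      he <- ifelse(na > 1L, he * na / (na - 1L), he)
    }
    data.frame(group = g, n_samples = length(samp), n_sites = sum(use),
               Ho = mean(cs$h[use]),
               He = mean(he),
               Pn = mean(cs$p[use] > 0 & cs$p[use] < 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Method-of-moments inbreeding coefficient F
#'
#' Per sample, over its group's polymorphic sites:
#' `F = (O_hom - E_hom) / (L - E_hom)` where `O_hom` is the number of
#' homozygous calls of the sample, `L` its number of non-missing calls, and
#' `E_hom = sum_j (1 - 2 p_j (1 - p_j) n_j / (n_j - 1))` the expected
#' homozygote count under Hardy-Weinberg given the group's allele frequency
#' `p_j` and non-missing allele count `n_j` at each site. Sites monomorphic
#' within the group are excluded (F is invariant to them).
#'
#' @param gm a [geno_matrix()].
#' @param pm a `pop_map`.
#' @return List with `per_sample` (sample, group, O_hom, E_hom, L, F) and
#'   `per_group` (group, F_mean over defined values).
#' @export
inbreeding_f <- function(gm, pm) {
  rows <- lapply(unique(pm$group), function(g) {
    samp <- pm$sample[pm$group == g]
    cs <- group_site_counts(gm, samp)
    poly <- !is.na(cs$p) & cs$p > 0 & cs$p < 1 & cs$n_allele > 1L
    e_site <- 1 - 2 * cs$p * (1 - cs$p) * cs$n_allele / (cs$n_allele - 1L)
    d <- dosage(gm)[, samp, drop = FALSE]
    do.call(rbind, lapply(seq_along(samp), function(j) {
      use <- poly & !is.na(d[, j])
      L <- sum(use)
      O <- sum(d[use, j] != 1L)
      E <- sum(e_site[use])
      f <- if (abs(L - E) < 1e-12) {
        warning("F undefined for sample ", samp[j], " (L - E_hom = 0)")
        NA_real_
      } else (O - E) / (L - E)
      data.frame(sample = samp[j], group = g, O_hom = O, E_hom = E,
                 L = L, F = f, stringsAsFactors = FALSE)
    }))
  })
  per_sample <- do.call(rbind, rows)
  per_group <- stats::aggregate(F ~ group, per_sample, mean,
                                na.action = stats::na.omit)
  names(per_group)[2] <- "F_mean"
  list(per_sample = per_sample, per_group = per_group)
}

#' Combined per-group diversity summary
#'
#' [het_summary()] merged with the group means of [inbreeding_f()].
#' @inheritParams het_summary
#' @return Data frame (group, n_samples, n_sites, Ho, He, Pn, F_mean).
#' @export
diversity_summary <- function(gm, pm) {
  merge(het_summary(gm, pm), inbreeding_f(gm, pm)$per_group,
        by = "group", all.x = TRUE, sort = FALSE)
}

# per-site nucleotide diversity for one group: unbiased mean pairwise
# difference c_ref * c_alt / choose(n, 2); NA where n < 2 alleles
pi_site <- function(cs) {
  n <- cs$n_allele
  ifelse(n >= 2L, cs$c_ref * cs$c_alt / (n * (n - 1) / 2), NA_real_)
}

#' Windowed nucleotide diversity (theta-pi)
#'
#' Per site within the group, with non-missing allele counts
#' `(c_ref, c_alt)` and `n = c_ref + c_alt >= 2`, the site diversity is
#' `c_ref * c_alt / C(n, 2)` (the mean pairwise difference among sampled
#' haplotypes). Window diversity is the sum of site values divided by the
#' full window span in bp; sites with fewer than two sampled alleles are
#' skipped. Sites contribute to every window containing them (the 50/25
#' scheme double-counts by design).
#'
#' @param gm a [geno_matrix()].
#' @param pm a `pop_map`.
#' @param group a group or superset label (see [resolve_samples()]).
#' @param windows window table from [make_windows()].
#' @return Data frame (chrom, start, end, index, truncated, group, n_snps,
#'   pi); `pi = 0` where a window has no usable SNPs.
#' @export
windowed_pi <- function(gm, pm, group, windows) {
  samp <- resolve_samples(pm, group)
  cs <- group_site_counts(gm, samp)
  ps <- pi_site(cs)
  usable <- which(!is.na(ps))
  map <- site_window_map(gm$chrom[usable], gm$pos[usable], windows)
  w <- factor(map$window, levels = seq_len(nrow(windows)))
  pi_sum <- as.numeric(tapply(ps[usable][map$site], w, sum, default = 0))
  n_snp <- as.integer(tapply(rep(1L, length(map$site)), w, sum, default = 0L))
  pi_sum[is.na(pi_sum)] <- 0; n_snp[is.na(n_snp)] <- 0L
  out <- windows
  out$group <- group
  out$n_snps <- n_snp
  out$pi <- pi_sum / (windows$end - windows$start + 1)
  out
}
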