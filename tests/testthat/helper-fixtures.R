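# Shared fixtures and independent oracles, all built in code.

# small genotype matrix from a dosage matrix (biallelic, unphased)
gm_from_dosage <- function(d, chrom = "chr1", pos = NULL, contig_len = NULL) {
  d <- as.matrix(d)
  if (is.null(pos)) pos <- seq_len(nrow(d)) * 10L
  a1 <- matrix(pmin(d, 1L), nrow(d), ncol(d))
  a2 <- matrix(pmax(d - 1L, 0L), nrow(d), ncol(d))
  a1[is.na(d)] <- NA_integer_; a2[is.na(d)] <- NA_integer_
  ids <- colnames(d)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(ncol(d)))
  cl <- if (!is.null(contig_len)) stats::setNames(rep(contig_len,
    length(unique(chrom))), unique(chrom)) else NULL
  geno_matrix(chrom = rep(chrom, length.out = nrow(d)), pos = pos,
              ref = rep("A", nrow(d)), alt = rep("C", nrow(d)),
              a1 = a1, a2 = a2, phased = FALSE, sample_ids = ids,
              contig_lengths = cl)
}

# phased two-site matrix from haplotype pairs; rows = 2 sites,
# haps is a list of length-2 0/1 vectors, one per haplotype; haplotypes
# are paired consecutively into diploids
gm_from_haps <- function(haps) {
  stopifnot(length(haps) %% 2 == 0)
  h <- do.call(cbind, haps)   # 2 x n_hap
  odd <- seq(1, ncol(h), by = 2)
  geno_matrix(chrom = c("chr1", "chr1"), pos = c(100L, 200L),
              ref = c("A", "A"), alt = c("C", "C"),
              a1 = h[, odd, drop = FALSE], a2 = h[, odd + 1, drop = FALSE],
              phased = TRUE,
              sample_ids = sprintf("s%d", seq_along(odd)))
}

pm_one_group <- function(gm, group = "g1", superset = "native") {
  pop_map(data.frame(sample = gm$sample_ids, group = group,
                     superset = superset, stringsAsFactors = FALSE))
}

# Independent Weir-Cockerham oracle via the nested-ANOVA mean squares
# (E[MSG]=c, E[MSI]=c+2b, E[MSP]=c+2b+2*nc*a), a different route than the
# closed-form component equations in the package.
wc_anova_oracle <- function(g1, g2) {
  y <- list(g1, g2)
  r <- 2L
  n <- vapply(y, length, integer(1))
  p <- vapply(y, function(g) mean(g) / 2, numeric(1))
  pbar <- sum(n * p) / sum(n)
  SSG <- sum(unlist(lapply(y, function(g) ifelse(g == 1L, 0.5, 0))))
  MSG <- SSG / sum(n)
  SSI <- 2 * sum(unlist(mapply(function(g, pi) (g / 2 - pi)^2, y, p)))
  MSI <- SSI / sum(n - 1L)
  SSP <- 2 * sum(n * (p - pbar)^2)
  MSP <- SSP / (r - 1L)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1L)
  c(a = (MSP - MSI) / (2 * nc), b = (MSI - MSG) / 2, c = MSG)
}

# brute-force per-site nucleotide diversity: mean pairwise difference over
# all haplotype pairs
pi_site_bruteforce <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0L; pairs <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diffs <- diffs + (alleles[i] != alleles[j])
    pairs <- pairs + 1L
  }
  diffs / pairs
}

# random genotype matrix for round-trip property tests
random_gm <- function(seed, n_sites = 30, n_samples = 4) {
  set.seed(seed)
  pos <- sort(sample.int(10000L, n_sites))
  alt <- sample(c("C", "G", "C,T"), n_sites, replace = TRUE,
                prob = c(0.45, 0.45, 0.1))
  n_al <- ifelse(nchar(alt) > 1, 2L, 1L)
  a1 <- matrix(NA_integer_, n_sites, n_samples)
  a2 <- matrix(NA_integer_, n_sites, n_samples)
  for (i in seq_len(n_sites)) {
    a1[i, ] <- sample(0:n_al[i], n_samples, replace = TRUE)
    a2[i, ] <- sample(0:n_al[i], n_samples, replace = TRUE)
  }
  miss <- matrix(runif(n_sites * n_samples) < 0.1, n_sites, n_samples)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  phased <- matrix(runif(n_sites * n_samples) < 0.5, n_sites, n_samples)
  phased[miss] <- FALSE
  gq <- if (seed %% 2 == 0)
    matrix(sample(c(NA, 10:99), n_sites * n_samples, replace = TRUE),
           n_sites, n_samples) else NULL
  if (!is.null(gq)) gq[miss] <- NA
  mq <- if (seed %% 3 == 0)
    sample(c(NA, seq(20, 60, by = 0.5)), n_sites, replace = TRUE) else NULL
  chrom <- rep(c("chr1", "chr2"),
               c(ceiling(n_sites / 2), floor(n_sites / 2)))
  geno_matrix(chrom = chrom,
              pos = pos, ref = rep("A", n_sites), alt = alt,
              a1 = a1, a2 = a2, phased = phased,
              sample_ids = sprintf("ind%02d", seq_len(n_samples)),
              gq = gq, mq = mq,
              contig_lengths = c(chr1 = 10000, chr2 = 10000))
}

gm_identical <- function(a, b) popgenscan:::gm_equal(a, b)

write_popmap_tsv <- function(pm, path) {
  utils::write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

files_byte_identical <- function(dir1, dir2) {
  f1 <- sort(list.files(dir1)); f2 <- sort(list.files(dir2))
  if (!identical(f1, f2)) return(FALSE)
  all(vapply(f1, function(f)
    identical(readBin(file.path(dir1, f), "raw", file.size(file.path(dir1, f))),
              readBin(file.path(dir2, f), "raw", file.size(file.path(dir2, f)))),
    logical(1)))
}
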