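#' Diploid genotype matrix
#'
#' The central container of the package: an ordered set of SNP sites
#' (chromosome, 1-based position, REF/ALT alleles) crossed with an ordered
#' set of samples, holding the two allele indices of every diploid call.
#' Missing calls are `NA`. Optional per-genotype qualities (`gq`), per-site
#' mapping quality (`mq`) and chromosome lengths travel with the matrix so
#' that filters and window construction can use them.
#'
#' Sites must be sorted by chromosome and strictly increasing position
#' within each chromosome. Alt-allele dosage (0/1/2) is defined only for
#' biallelic sites; [dosage()] returns `NA` for multiallelic ones.
#'
#' @param chrom character vector, per-site chromosome label.
#' @param pos integer vector, per-site 1-based position (bp).
#' @param ref,alt character vectors of REF and ALT allele strings; multiple
#'   ALT alleles are comma-separated as in VCF.
#' @param a1,a2 integer matrices (sites x samples) of first/second allele
#'   indices (0 = REF, 1 = first ALT, ...); `NA` = missing call.
#' @param phased logical matrix (sites x samples), or a single logical
#'   recycled to all calls.
#' @param sample_ids character vector of unique sample names.
#' @param gq optional numeric matrix (sites x samples) of genotype qualities.
#' @param mq optional numeric vector of per-site mapping qualities.
#' @param contig_lengths optional named numeric vector of chromosome lengths.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(chrom, pos, ref, alt, a1, a2, phased = FALSE,
                        sample_ids = colnames(a1), gq = NULL, mq = NULL,
                        contig_lengths = NULL) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  n_sites <- length(pos)
  n_samples <- length(sample_ids)
  if (is.null(sample_ids)) stop("sample_ids required")
  if (length(phased) == 1L) {
    phased <- matrix(as.logical(phased), n_sites, n_samples)
  }
  gm <- structure(list(
    sample_ids = as.character(sample_ids),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    a1 = a1, a2 = a2,
    phased = phased,
    gq = gq,
    mq = if (!is.null(mq)) as.numeric(mq) else NULL,
    contig_lengths = contig_lengths
  ), class = "geno_matrix")
  validate_geno_matrix(gm)
  gm
}

validate_geno_matrix <- function(gm) {
  ns <- length(gm$pos); nm <- length(gm$sample_ids)
  if (anyDuplicated(gm$sample_ids))
    stop("duplicate sample name: ",
         paste(unique(gm$sample_ids[duplicated(gm$sample_ids)]), collapse = ", "))
  for (f in c("chrom", "ref", "alt"))
    if (length(gm[[f]]) != ns) stop("field '", f, "' has wrong length")
  for (f in c("a1", "a2", "phased"))
    if (!all(dim(gm[[f]]) == c(ns, nm)))
      stop("matrix '", f, "' must be sites x samples (", ns, " x ", nm, ")")
  if (!is.null(gm$gq) && !all(dim(gm$gq) == c(ns, nm)))
    stop("gq must be sites x samples")
  if (!is.null(gm$mq) && length(gm$mq) != ns) stop("mq has wrong length")
  if (!is.null(gm$gq) && any(gm$gq < 0, na.rm = TRUE)) stop("gq must be non-negative")
  if (!is.null(gm$mq) && any(gm$mq < 0, na.rm = TRUE)) stop("mq must be non-negative")
  # strictly increasing positions within chromosome
  if (ns > 1L) {
    same <- gm$chrom[-1L] == gm$chrom[-ns]
    if (any(same & diff(gm$pos) <= 0L))
      stop("positions must be strictly increasing within each chromosome")
  }
  invisible(gm)
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$pos), "sites x", length(x$sample_ids), "samples\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  cat("  multiallelic sites:", sum(n_alt_alleles(x) > 1L), "\n")
  cat("  GQ:", !is.null(x$gq), " MQ:", !is.null(x$mq),
      " contig lengths:", !is.null(x$contig_lengths), "\n")
  invisible(x)
}

#' Number of sites / samples
#' @param gm a [geno_matrix()].
#' @return integer count.
#' @export
n_sites <- function(gm) length(gm$pos)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' Per-site number of ALT alleles
#' @param gm a [geno_matrix()].
#' @return integer vector; 1 for biallelic sites.
#' @export
n_alt_alleles <- function(gm) {
  ifelse(gm$alt == "" | gm$alt == ".", 0L,
         lengths(strsplit(gm$alt, ",", fixed = TRUE)))
}

#' Alt-allele dosage matrix
#'
#' Returns the sites x samples matrix of alt-allele dosages in 0/1/2 with
#' `NA` for missing calls. Rows of multiallelic sites are all-`NA`: dosage
#' is defined for biallelic sites only.
#' @param gm a [geno_matrix()].
#' @return integer matrix, sites x samples, dimnames `(NULL, sample_ids)`.
#' @export
dosage <- function(gm) {
  d <- gm$a1 + gm$a2
  d[n_alt_alleles(gm) > 1L, ] <- NA_integer_
  colnames(d) <- gm$sample_ids
  d
}

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param sites integer or logical index of sites to keep (order preserved).
#' @param samples character names, or integer/logical index, of samples.
#' @return A new `geno_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_along(gm$pos)
  if (is.logical(sites)) sites <- which(sites)
  if (is.null(samples)) {
    samples <- seq_along(gm$sample_ids)
  } else if (is.character(samples)) {
    idx <- match(samples, gm$sample_ids)
    if (anyNA(idx)) stop("unknown sample: ", paste(samples[is.na(idx)], collapse = ", "))
    samples <- idx
  } else if (is.logical(samples)) samples <- which(samples)
  geno_matrix(
    chrom = gm$chrom[sites], pos = gm$pos[sites],
    ref = gm$ref[sites], alt = gm$alt[sites],
    a1 = gm$a1[sites, samples, drop = FALSE],
    a2 = gm$a2[sites, samples, drop = FALSE],
    phased = gm$phased[sites, samples, drop = FALSE],
    sample_ids = gm$sample_ids[samples],
    gq = if (!is.null(gm$gq)) gm$gq[sites, samples, drop = FALSE] else NULL,
    mq = if (!is.null(gm$mq)) gm$mq[sites] else NULL,
    contig_lengths = gm$contig_lengths
  )
}

#' Chromosome lengths, with fallback
#'
#' Contig lengths from the VCF header when present, otherwise the maximum
#' observed position per chromosome (which truncates trailing windows).
#' @param gm a [geno_matrix()].
#' @return named numeric vector of lengths (bp).
#' @export
contig_lengths <- function(gm) {
  if (!is.null(gm$contig_lengths)) return(gm$contig_lengths)
  tapply(gm$pos, factor(gm$chrom, levels = unique(gm$chrom)), max)[unique(gm$chrom)]
}

gm_equal <- function(a, b) {
  identical(a$sample_ids, b$sample_ids) && identical(a$chrom, b$chrom) &&
    identical(a$pos, b$pos) && identical(a$ref, b$ref) &&
    identical(a$alt, b$alt) &&
    identical(unname(a$a1), unname(b$a1)) && identical(unname(a$a2), unname(b$a2)) &&
    identical(unname(a$phased), unname(b$phased)) &&
    (is.null(a$gq) == is.null(b$gq)) &&
    (is.null(a$gq) || isTRUE(all.equal(unname(a$gq), unname(b$gq)))) &&
    (is.null(a$mq) == is.null(b$mq)) &&
    (is.null(a$mq) || isTRUE(all.equal(a$mq, b$mq)))
}
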