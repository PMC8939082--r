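#' Weir-Cockerham variance components for one biallelic site
#'
#' Given, for each of r populations, the number of genotyped diploids
#' `n_i`, the alt-allele frequency `p_i` and the observed heterozygote
#' proportion `h_i`, computes the among-population (a),
#' among-individual-within-population (b) and within-individual (c)
#' variance components of the classic moment estimator. Site-wise
#' `F_ST = a / (a + b + c)` may be negative; the windowed and genome-wide
#' "weighted" estimator is the ratio of sums.
#'
#' @param n integer vector of genotyped diploids per population.
#' @param p numeric vector of alt-allele frequencies per population.
#' @param h numeric vector of observed heterozygote proportions.
#' @return List with `a`, `b`, `c` and the intermediate quantities
#'   (`nbar`, `nc`, `pbar`, `s2`, `hbar`, `r`).
#' @export
wc_site_components <- function(n, p, h) {
  r <- length(n)
  stopifnot(length(p) == r, length(h) == r, r >= 2)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c, nbar = nbar, nc = nc, pbar = pbar,
       s2 = s2, hbar = hbar, r = r)
}

# vectorized two-population components over all sites; cs_a/cs_b from
# group_site_counts(). Returns data frame with a, b, c and usability.
wc_components_sites <- function(cs_a, cs_b, n_alt) {
  r <- 2
  n1 <- cs_a$n_dip; n2 <- cs_b$n_dip
  nbar <- (n1 + n2) / r
  usable <- n1 >= 1L & n2 >= 1L & nbar > 1 & n_alt == 1L
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * cs_a$p + n2 * cs_b$p) / (r * nbar)
  s2 <- (n1 * (cs_a$p - pbar)^2 + n2 * (cs_b$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * cs_a$h + n2 * cs_b$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  mono <- pbar %in% c(0, 1)           # monomorphic across both groups
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  usable <- usable & !mono
  data.frame(a = a, b = b, c = cc, usable = usable)
}

#' Windowed and genome-wide weighted F_ST
#'
#' Per window, `F_ST = sum(a) / sum(a + b + c)` over usable sites (the
#' ratio-of-sums "weighted" estimator, robust to unequal sample sizes);
#' the genome-wide value is computed the same way over all usable sites.
#' Sites are usable when both groups have at least one genotyped diploid,
#' mean sample size exceeds one, the site is biallelic and not monomorphic
#' across the two groups pooled. Windows without usable sites are flagged
#' and excluded from outlier ranking. Negative window values are retained;
#' clamping would distort empirical quantiles. `mean_of_sites` gives the
#' alternative mean of per-site ratios.
#'
#' @param gm a [geno_matrix()].
#' @param pm a `pop_map`.
#' @param group_a,group_b group or superset labels of the contrast (must
#'   resolve to disjoint sample sets).
#' @param windows window table from [make_windows()].
#' @param mean_of_sites also report the mean of per-site a/(a+b+c).
#' @return List: `windows` (window table + n_sites_fst, fst, flag
#'   no_usable_sites), `genome_fst`, `n_sites_usable`, `n_sites_skipped`.
#' @export
windowed_weighted_fst <- function(gm, pm, group_a, group_b, windows,
                                  mean_of_sites = FALSE) {
  if (identical(group_a, group_b)) stop("contrast groups must differ")
  sa <- resolve_samples(pm, group_a)
  sb <- resolve_samples(pm, group_b)
  if (length(intersect(sa, sb)))
    stop("contrast groups overlap: ", paste(intersect(sa, sb), collapse = ", "))
  comp <- wc_components_sites(group_site_counts(gm, sa),
                              group_site_counts(gm, sb), n_alt_alleles(gm))
  use <- which(comp$usable)
  map <- site_window_map(gm$chrom[use], gm$pos[use], windows)
  w <- factor(map$window, levels = seq_len(nrow(windows)))
  num <- as.numeric(tapply(comp$a[use][map$site], w, sum, default = 0))
  den <- as.numeric(tapply((comp$a + comp$b + comp$c)[use][map$site], w,
                           sum, default = 0))
  nst <- as.integer(tapply(rep(1L, length(map$site)), w, sum, default = 0L))
  num[is.na(num)] <- 0; den[is.na(den)] <- 0; nst[is.na(nst)] <- 0L
  out <- windows
  out$n_sites_fst <- nst
  out$no_usable_sites <- nst == 0L | den == 0
  out$fst <- ifelse(out$no_usable_sites, NA_real_, num / den)
  if (mean_of_sites) {
    ratio <- comp$a[use] / (comp$a + comp$b + comp$c)[use]
    ok <- is.finite(ratio)
    ms <- as.numeric(tapply(ratio[ok][map$site %in% which(ok)],
                            factor(map$window[map$site %in% which(ok)],
                                   levels = seq_len(nrow(windows))),
                            mean))
    out$fst_mean_of_sites <- ms
  }
  list(windows = out,
       genome_fst = sum(comp$a[use]) / sum((comp$a + comp$b + comp$c)[use]),
       n_sites_usable = length(use),
       n_sites_skipped = n_sites(gm) - length(use))
}

#' Windowed log2 diversity ratio
#'
#' `log2(pi_a / pi_b)` per window where both diversities are positive;
#' windows with either value zero are flagged `zero_pi` and excluded from
#' outlier ranking (their count is reported by the scan).
#'
#' @param pi_a,pi_b outputs of [windowed_pi()] for the two groups, on
#'   identical windows.
#' @return Data frame: the window columns plus `pi_a`, `pi_b`,
#'   `log2_ratio`, `zero_pi`.
#' @export
log2_pi_ratio <- function(pi_a, pi_b) {
  if (!identical(pi_a[, c("chrom", "start", "end")],
                 pi_b[, c("chrom", "start", "end")]))
    stop("window sets of the two groups do not match")
  out <- pi_a[, c("chrom", "start", "end", "index", "truncated")]
  out$pi_a <- pi_a$pi
  out$pi_b <- pi_b$pi
  out$zero_pi <- out$pi_a == 0 | out$pi_b == 0
  out$log2_ratio <- ifelse(out$zero_pi, NA_real_, log2(out$pi_a / out$pi_b))
  out
}

#' Empirical-quantile outlier flagging
#'
#' Flags the `k = ceiling(upper_frac * N)` largest of the `N` usable
#' (non-NA) values, breaking ties by genomic order (earlier window first).
#' The reported threshold is the smallest flagged value. This nearest-rank
#' convention makes the flagged count exact by construction.
#'
#' @param values numeric vector of per-window statistics (NA = unusable).
#' @param upper_frac upper tail fraction in (0, 1).
#' @return List: `threshold`, `flagged` (indices into `values`), `k`,
#'   `n_usable`.
#' @export
empirical_outliers <- function(values, upper_frac) {
  stopifnot(upper_frac > 0, upper_frac < 1)
  usable <- which(!is.na(values))
  if (!length(usable)) stop("no usable values to rank")
  k <- ceiling(upper_frac * length(usable))
  if (length(unique(values[usable])) == 1L)
    warning("all values equal; flagging first ", k, " windows in genomic order")
  ord <- usable[order(-values[usable], usable)]
  flagged <- sort(ord[seq_len(k)])
  list(threshold = min(values[flagged]), flagged = flagged, k = k,
       n_usable = length(usable))
}

#' Call candidate sweep regions from the two-statistic scan
#'
#' Flags the top `fst_frac` of windowed F_ST and the `ratio_frac` tail of
#' the log2 diversity ratio (upper tail by default: high
#' native-over-commercial ratios mark commercial-side diversity loss;
#' `ratio_tail = "lower"` selects the opposite contrast), merges
#' overlapping or book-ended outlier windows into regions per statistic,
#' and intersects the two region sets.
#'
#' @param fst_windows `windows` element of [windowed_weighted_fst()].
#' @param ratio_windows output of [log2_pi_ratio()].
#' @param fst_frac upper-tail fraction for F_ST (default 0.05).
#' @param ratio_frac tail fraction for the log2 ratio (default 0.01).
#' @param ratio_tail `"upper"` or `"lower"`.
#' @return A `sweep_report` list: `thresholds`, `outlier_windows` (per
#'   statistic), `regions_fst`, `regions_ratio`, `regions_intersection`
#'   (data frames chrom/start/end, 1-based inclusive), `counts`.
#' @export
call_candidate_regions <- function(fst_windows, ratio_windows,
                                   fst_frac = 0.05, ratio_frac = 0.01,
                                   ratio_tail = c("upper", "lower")) {
  ratio_tail <- match.arg(ratio_tail)
  of <- empirical_outliers(fst_windows$fst, fst_frac)
  rv <- ratio_windows$log2_ratio
  if (ratio_tail == "lower") rv <- -rv
  orr <- empirical_outliers(rv, ratio_frac)
  ratio_threshold <- if (ratio_tail == "lower") -orr$threshold else orr$threshold
  reg_f <- merge_intervals(fst_windows[of$flagged, c("chrom", "start", "end")])
  reg_r <- merge_intervals(ratio_windows[orr$flagged, c("chrom", "start", "end")])
  inter <- if (nrow(reg_f) && nrow(reg_r)) {
    gr <- GenomicRanges::intersect(
      GenomicRanges::GRanges(reg_f$chrom, IRanges::IRanges(reg_f$start, reg_f$end)),
      GenomicRanges::GRanges(reg_r$chrom, IRanges::IRanges(reg_r$start, reg_r$end)))
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  structure(list(
    thresholds = c(fst = of$threshold, log2_ratio = ratio_threshold),
    outlier_windows = list(fst = of$flagged, ratio = orr$flagged),
    regions_fst = reg_f, regions_ratio = reg_r,
    regions_intersection = inter,
    counts = c(n_windows_fst_usable = of$n_usable, k_fst = of$k,
               n_windows_ratio_usable = orr$n_usable, k_ratio = orr$k,
               n_windows_fst_excluded = sum(is.na(fst_windows$fst)),
               n_windows_zero_pi = sum(ratio_windows$zero_pi))),
    class = "sweep_report")
}

#' Read gene intervals from BED
#'
#' BED is 0-based half-open; coordinates are converted to the package's
#' 1-based inclusive convention at this boundary. The name column (4th) is
#' required.
#'
#' @param path BED file path.
#' @return Data frame (chrom, start, end, name), 1-based inclusive.
#' @export
read_genes_bed <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("gene BED needs 4 columns (chrom, start, end, name)")
  data.frame(chrom = as.character(raw[[1L]]), start = raw[[2L]] + 1L,
             end = raw[[3L]], name = as.character(raw[[4L]]),
             stringsAsFactors = FALSE)
}

#' Annotate candidate regions with overlapping genes
#'
#' Every gene overlapping any merged region by at least 1 bp is listed
#' once, with the ids of its supporting regions and which statistics
#' support them. Regions on chromosomes absent from the annotation are
#' reported unannotated with a warning.
#'
#' @param report a `sweep_report` from [call_candidate_regions()].
#' @param genes gene intervals from [read_genes_bed()] (1-based inclusive);
#'   an empty data frame yields an empty gene table.
#' @return List: `genes` (gene, chrom, gene_start, gene_end, region_ids,
#'   statistics, overlap_bp), `regions` (all regions with ids, statistic
#'   and n_genes).
#' @export
annotate_regions <- function(report, genes) {
  regs <- rbind(
    if (nrow(report$regions_fst))
      cbind(report$regions_fst, statistic = "fst"),
    if (nrow(report$regions_ratio))
      cbind(report$regions_ratio, statistic = "log2_ratio"),
    if (nrow(report$regions_intersection))
      cbind(report$regions_intersection, statistic = "intersection"))
  if (is.null(regs) || nrow(regs) == 0L)
    return(list(genes = data.frame(), regions = data.frame()))
  regs$region_id <- sprintf("%s_%s:%d-%d", regs$statistic, regs$chrom,
                            as.integer(regs$start), as.integer(regs$end))
  regs$n_genes <- 0L
  gene_tab <- data.frame(gene = character(0), chrom = character(0),
                         gene_start = numeric(0), gene_end = numeric(0),
                         region_ids = character(0), statistics = character(0),
                         overlap_bp = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(genes) && nrow(genes)) {
    unknown <- setdiff(unique(regs$chrom), unique(genes$chrom))
    if (length(unknown))
      warning("no annotation for chromosome(s): ",
              paste(unknown, collapse = ", "), "; regions left unannotated")
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    rr <- GenomicRanges::GRanges(regs$chrom,
                                 IRanges::IRanges(regs$start, regs$end))
    ov <- GenomicRanges::findOverlaps(gg, rr)
    if (length(ov)) {
      gi <- S4Vectors::queryHits(ov); ri <- S4Vectors::subjectHits(ov)
      olap <- pmin(genes$end[gi], regs$end[ri]) -
        pmax(genes$start[gi], regs$start[ri]) + 1
      tb <- table(ri)
      regs$n_genes[as.integer(names(tb))] <- as.integer(tb)
      gene_tab <- do.call(rbind, lapply(unique(gi), function(g) {
        sel <- gi == g
        data.frame(gene = genes$name[g], chrom = genes$chrom[g],
                   gene_start = genes$start[g], gene_end = genes$end[g],
                   region_ids = paste(regs$region_id[ri[sel]], collapse = ","),
                   statistics = paste(sort(unique(regs$statistic[ri[sel]])),
                                      collapse = ","),
                   overlap_bp = max(olap[sel]), stringsAsFactors = FALSE)
      }))
    }
  }
  list(genes = gene_tab, regions = regs)
}
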