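#' Runs-of-homozygosity detection
#'
#' Scanning-window algorithm in the PLINK tradition: a window of
#' `scan_window_snps` consecutive SNPs "hits" when it contains at most
#' `max_het_per_window` heterozygous and at most `max_miss_per_window`
#' missing calls; every SNP's hit proportion is the fraction of windows
#' covering it that hit, and SNPs at proportion `>= hit_frac` are
#' run-eligible. Maximal runs of eligible SNPs, delimited at heterozygous
#' calls, are reported when they span at least `min_kb` kb and contain at
#' least `min_snps` SNPs. Segment coordinates are delimited by the first
#' and last SNP of the run. Segments are classed `0.1-0.4Mb` / `>0.4Mb`,
#' with runs beyond 1 Mb flagged separately.
#'
#' @param gm a [geno_matrix()].
#' @param samples sample names to scan; default all.
#' @param min_kb minimum segment length in kb.
#' @param min_snps minimum SNPs per segment.
#' @param scan_window_snps scanning window size in SNPs.
#' @param max_het_per_window,max_miss_per_window window hit tolerances.
#' @param hit_frac minimum hit proportion for a SNP to be run-eligible.
#' @return Data frame (sample, chrom, start, end, n_snps, length_kb,
#'   length_class, over_1mb); zero rows when nothing is found.
#' @export
detect_roh <- function(gm, samples = NULL, min_kb = 100, min_snps = 50,
                       scan_window_snps = 50, max_het_per_window = 1,
                       max_miss_per_window = 5, hit_frac = 0.05) {
  if (is.null(samples)) samples <- gm$sample_ids
  miss_id <- setdiff(samples, gm$sample_ids)
  if (length(miss_id)) stop("unknown sample: ", paste(miss_id, collapse = ", "))
  D <- dosage(gm)
  segs <- list()
  for (s in samples) {
    d <- D[, s]
    for (ch in unique(gm$chrom)) {
      idx <- which(gm$chrom == ch)
      if (!length(idx)) next
      het <- !is.na(d[idx]) & d[idx] == 1L
      mis <- is.na(d[idx])
      S <- length(idx)
      W <- min(scan_window_snps, S)
      nw <- S - W + 1L
      ch_het <- c(0L, cumsum(het)); ch_mis <- c(0L, cumsum(mis))
      wh <- ch_het[(W + 1L):(S + 1L)] - ch_het[1L:nw]
      wm <- ch_mis[(W + 1L):(S + 1L)] - ch_mis[1L:nw]
      hit <- wh <= max_het_per_window & wm <= max_miss_per_window
      ch_hit <- c(0L, cumsum(hit))
      k <- seq_len(S)
      a <- pmax(1L, k - W + 1L); b <- pmin(k, nw)
      prop <- (ch_hit[b + 1L] - ch_hit[a]) / (b - a + 1L)
      elig <- prop >= hit_frac & !het
      r <- rle(elig)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (q in which(r$values)) {
        i1 <- idx[starts[q]]; i2 <- idx[ends[q]]
        len <- gm$pos[i2] - gm$pos[i1] + 1L
        nsnp <- ends[q] - starts[q] + 1L
        if (len >= min_kb * 1000 && nsnp >= min_snps) {
          segs[[length(segs) + 1L]] <- data.frame(
            sample = s, chrom = ch, start = gm$pos[i1], end = gm$pos[i2],
            n_snps = nsnp, length_kb = len / 1000,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(segs))
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length_kb = numeric(0),
                      length_class = character(0), over_1mb = logical(0)))
  out <- do.call(rbind, segs)
  out$length_class <- ifelse(out$length_kb < 400, "0.1-0.4Mb", ">0.4Mb")
  out$over_1mb <- out$length_kb > 1000
  out
}

#' Per-group ROH summary
#'
#' Counts and mean lengths per length class, pooled by group, plus a
#' per-sample table. The `>1Mb` count is a subset of the `>=0.4Mb` class,
#' reported separately.
#'
#' @param segments output of [detect_roh()].
#' @param pm a `pop_map`.
#' @return List with `per_group` (group, n_0.1_0.4Mb, n_ge_0.4Mb, n_gt_1Mb,
#'   mean_kb_0.1_0.4Mb, mean_kb_ge_0.4Mb) and `per_sample`.
#' @export
roh_summary <- function(segments, pm) {
  tab <- function(df, key) {
    short <- df$length_class == "0.1-0.4Mb"
    data.frame(n_0.1_0.4Mb = sum(short),
               n_ge_0.4Mb = sum(!short),
               n_gt_1Mb = sum(df$over_1mb),
               mean_kb_0.1_0.4Mb = if (any(short)) mean(df$length_kb[short]) else NA_real_,
               mean_kb_ge_0.4Mb = if (any(!short)) mean(df$length_kb[!short]) else NA_real_)
  }
  segs <- merge(segments, pm[, c("sample", "group")], by = "sample",
                all.x = TRUE, sort = FALSE)
  per_group <- do.call(rbind, lapply(unique(pm$group), function(g) {
    cbind(group = g, tab(segs[!is.na(segs$group) & segs$group == g, ]))
  }))
  per_sample <- do.call(rbind, lapply(unique(pm$sample), function(s) {
    cbind(sample = s, tab(segs[segs$sample == s, ]))
  }))
  list(per_group = per_group, per_sample = per_sample)
}
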