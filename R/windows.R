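#' Sliding genomic windows
#'
#' Per chromosome, windows start at 1, 1 + step, 1 + 2*step, ... while the
#' start does not exceed the chromosome length; each window ends at
#' `min(start + size - 1, length)`. Trailing truncated windows are included
#' and flagged so users may drop them. Defaults are the 50 kb / 25 kb
#' sliding scheme.
#'
#' @param contig_lengths named numeric vector of chromosome lengths (bp).
#' @param size window size in bp.
#' @param step step between window starts in bp.
#' @return Data frame (chrom, start, end, index, truncated) with 1-based
#'   inclusive coordinates; `index` is a genome-wide ordinal.
#' @export
make_windows <- function(contig_lengths, size = 50000, step = 25000) {
  stopifnot(size > 0, step > 0)
  out <- lapply(names(contig_lengths), function(ch) {
    len <- contig_lengths[[ch]]
    starts <- seq(1, len, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + size - 1, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$index <- seq_len(nrow(out))
  out$truncated <- out$end - out$start + 1 < size
  out
}

# map sites to all windows containing them; returns two parallel integer
# vectors (site index, window index)
site_window_map <- function(chrom, pos, windows) {
  sites <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  wins <- GenomicRanges::GRanges(windows$chrom,
                                 IRanges::IRanges(windows$start, windows$end))
  ov <- GenomicRanges::findOverlaps(sites, wins)
  list(site = S4Vectors::queryHits(ov), window = S4Vectors::subjectHits(ov))
}

# merge 1-based inclusive intervals (overlapping or book-ended) per chrom
merge_intervals <- function(df) {
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0)))
  gr <- GenomicRanges::reduce(
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}
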