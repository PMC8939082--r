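#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (optionally bgzipped) and returns a
#' [geno_matrix()]. The GT FORMAT field is required; per-genotype GQ and the
#' per-site INFO/MQ mapping quality are read when present, as are
#' `##contig` header lengths. Site order is preserved; `./.` and `.|.`
#' become missing calls.
#'
#' @param path path to a VCF (.vcf or .vcf.gz) file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n_meta <- length(v@meta)
  fix <- v@fix
  samples <- colnames(v@gt)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample name in VCF: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("malformed VCF record at line ", n_meta + 1L + bad,
         ": non-numeric POS '", fix[bad, "POS"], "'")
  }
  if (nrow(fix) == 0L) {
    empty <- matrix(NA_integer_, 0L, length(samples),
                    dimnames = list(NULL, samples))
    return(geno_matrix(character(0), integer(0), character(0), character(0),
                       a1 = empty, a2 = empty,
                       phased = matrix(FALSE, 0L, length(samples)),
                       sample_ids = samples,
                       contig_lengths = parse_contig_meta(v@meta)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT FORMAT field")
  phased <- matrix(grepl("|", gt, fixed = TRUE), nrow(gt), ncol(gt))
  a1c <- sub("^([^/|]*).*$", "\\1", gt)
  a2c <- sub("^[^/|]*[/|]", "", gt)
  to_int <- function(x) {
    x[x == "." | x == "" | is.na(x)] <- NA_character_
    suppressWarnings(matrix(as.integer(x), nrow(gt), ncol(gt)))
  }
  a1 <- to_int(a1c); a2 <- to_int(a2c)
  phased[is.na(a1) & is.na(a2)] <- FALSE

  gq <- NULL
  if (any(grepl("(^|:)GQ(:|$)", v@gt[, "FORMAT"]))) {
    gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
    gq <- matrix(as.numeric(gq), nrow(gt), ncol(gt))
  }
  mq <- suppressWarnings(vcfR::extract.info(v, element = "MQ", as.numeric = TRUE))
  if (is.null(mq) || all(is.na(mq))) mq <- NULL

  geno_matrix(chrom = fix[, "CHROM"], pos = pos,
              ref = fix[, "REF"],
              alt = ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
              a1 = a1, a2 = a2, phased = phased, sample_ids = samples,
              gq = gq, mq = mq,
              contig_lengths = parse_contig_meta(v@meta))
}

parse_contig_meta <- function(meta) {
  ln <- grep("^##contig=", meta, value = TRUE)
  if (!length(ln)) return(NULL)
  ids <- sub('.*[<,]ID=([^,>]+).*', "\\1", ln)
  has_len <- grepl("length=", ln)
  if (!any(has_len)) return(NULL)
  lens <- rep(NA_real_, length(ln))
  lens[has_len] <- as.numeric(sub(".*length=([0-9]+).*", "\\1", ln[has_len]))
  stats::setNames(lens, ids)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits a deterministic plain-text VCF with GT (and GQ when present in the
#' matrix, MQ in INFO when present). Phased calls use the `|` separator.
#' `read_vcf(write_vcf(gm))` reproduces `gm`.
#'
#' @param gm a [geno_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popgenscan")
  if (!is.null(gm$contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(gm$contig_lengths),
                          as.integer(gm$contig_lengths)))
  if (!is.null(gm$mq))
    hdr <- c(hdr, "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">")
  hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (!is.null(gm$gq))
    hdr <- c(hdr, "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  ns <- n_sites(gm)
  if (ns > 0L) {
    sep <- ifelse(gm$phased, "|", "/")
    gt <- matrix(paste0(ifelse(is.na(gm$a1), ".", gm$a1), sep,
                        ifelse(is.na(gm$a2), ".", gm$a2)),
                 ns, n_samples(gm))
    fmt <- "GT"
    if (!is.null(gm$gq)) {
      gt <- matrix(paste0(gt, ":", ifelse(is.na(gm$gq), ".",
                                          format_num(gm$gq))), ns, n_samples(gm))
      fmt <- "GT:GQ"
    }
    info <- if (!is.null(gm$mq)) {
      ifelse(is.na(gm$mq), ".", paste0("MQ=", format_num(gm$mq)))
    } else rep(".", ns)
    body <- paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", ".",
                  info, fmt,
                  apply(gt, 1L, paste, collapse = "\t"),
                  sep = "\t")
  } else body <- character(0)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

format_num <- function(x) {
  out <- format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  out[is.na(x)] <- "."
  out
}

#' Read a sample-to-population map
#'
#' Tab-separated file with header columns `sample`, `group`, `superset`;
#' every sample appears once and supersets come from the closed vocabulary
#' `native` / `commercial` (the pooled contrast labels of the study design).
#'
#' @param path path to the TSV file.
#' @return A `pop_map` data frame with columns sample, group, superset.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (nrow(pm) == 0L) stop("population map is empty: ", path)
  pop_map(pm)
}

#' Construct/validate a population map
#' @param df data frame with columns sample, group, superset.
#' @return A validated `pop_map` data frame.
#' @export
pop_map <- function(df) {
  for (col in c("sample", "group", "superset"))
    if (!col %in% names(df)) stop("population map is missing column '", col, "'")
  if (anyDuplicated(df$sample))
    stop("sample listed twice in population map: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "))
  bad <- setdiff(unique(df$superset), c("native", "commercial"))
  if (length(bad))
    stop("unknown superset label(s): ", paste(bad, collapse = ", "),
         " (must be 'native' or 'commercial')")
  incons <- tapply(df$superset, df$group, function(x) length(unique(x)))
  if (any(incons > 1L))
    stop("group assigned to more than one superset: ",
         paste(names(incons)[incons > 1L], collapse = ", "))
  df <- df[, c("sample", "group", "superset")]
  class(df) <- c("pop_map", "data.frame")
  df
}

#' Resolve a group or superset label to sample names
#'
#' @param pm a `pop_map`.
#' @param label a group label or a superset label (`native`/`commercial`);
#'   supersets pool all their groups, mirroring the pooled
#'   indigenous-vs-commercial contrasts of the study design.
#' @return Character vector of sample names.
#' @export
resolve_samples <- function(pm, label) {
  hit <- pm$group == label | pm$superset == label
  if (!any(hit)) stop("label '", label, "' matches no group or superset in population map")
  pm$sample[hit]
}

#' Genotype- and mapping-quality filter
#'
#' Masks individual genotypes whose GQ falls below `gq_min` (the call becomes
#' missing; the site is retained) and removes whole sites whose INFO mapping
#' quality falls below `mq_min`. Sites or calls lacking the corresponding
#' quality field pass unchanged. Defaults are the conventional
#' GQ >= 40 / MQ >= 25 post-calling thresholds.
#'
#' @param gm a [geno_matrix()].
#' @param gq_min minimum genotype quality (calls below become missing).
#' @param mq_min minimum site mapping quality (sites below are dropped).
#' @return A list with `gm` (the filtered matrix) and `counts`, a named
#'   integer vector: `genotypes_masked`, `sites_removed_mq`, `sites_in`,
#'   `sites_out`.
#' @export
filter_quality <- function(gm, gq_min = 40, mq_min = 25) {
  stopifnot(gq_min >= 0, mq_min >= 0)
  n_in <- n_sites(gm)
  masked <- 0L
  if (!is.null(gm$gq)) {
    mask <- !is.na(gm$gq) & gm$gq < gq_min & !(is.na(gm$a1) & is.na(gm$a2))
    masked <- sum(mask)
    gm$a1[mask] <- NA_integer_
    gm$a2[mask] <- NA_integer_
    gm$phased[mask] <- FALSE
    gm$gq[mask] <- NA_real_
  }
  keep <- rep(TRUE, n_in)
  if (!is.null(gm$mq)) keep <- is.na(gm$mq) | gm$mq >= mq_min
  out <- gm_subset(gm, sites = keep)
  list(gm = out,
       counts = c(genotypes_masked = masked,
                  sites_removed_mq = n_in - sum(keep),
                  sites_in = n_in, sites_out = sum(keep)))
}

#' Biallelic and SNP-cluster site filter
#'
#' Removes sites with more than one ALT allele, then removes every SNP lying
#' in any `span`-bp interval that contains more than `max_in_span` SNPs
#' (the whole offending cluster is removed, the standard guard against
#' clustered alignment artefacts). Defaults implement the
#' "> 3 SNPs in a 10-bp window" rule.
#'
#' @param gm a [geno_matrix()] sorted by chromosome and position.
#' @param max_in_span maximum SNPs tolerated in any window of `span` bp.
#' @param span window width in bp.
#' @return A list with `gm` and `counts` (`sites_removed_multiallelic`,
#'   `sites_removed_cluster`, `sites_in`, `sites_out`).
#' @export
filter_biallelic_and_clusters <- function(gm, max_in_span = 3, span = 10) {
  n_in <- n_sites(gm)
  bi <- n_alt_alleles(gm) <= 1L
  gm2 <- gm_subset(gm, sites = bi)
  mark <- logical(n_sites(gm2))
  for (chr in unique(gm2$chrom)) {
    ii <- which(gm2$chrom == chr)
    p <- gm2$pos[ii]
    # any span-bp window with > max_in_span SNPs is anchored (w.l.o.g.) at a SNP
    last <- findInterval(p + span - 1L, p)
    cnt <- last - seq_along(p) + 1L
    for (k in which(cnt > max_in_span)) mark[ii[k:last[k]]] <- TRUE
  }
  out <- gm_subset(gm2, sites = !mark)
  list(gm = out,
       counts = c(sites_removed_multiallelic = n_in - sum(bi),
                  sites_removed_cluster = sum(mark),
                  sites_in = n_in, sites_out = n_sites(out)))
}
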