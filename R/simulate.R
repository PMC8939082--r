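#' Configuration for the structured-population genotype simulator
#'
#' The generator draws per-population allele frequencies under the
#' Balding-Nichols model (Beta around a uniform ancestral frequency with
#' variance `bn_F * p * (1 - p)`, so the divergence knob has the analytic
#' meaning of an expected F_ST), builds linkage by copying haplotypes as
#' mosaics of a finite founder pool, and can plant selective sweeps
#' (localized frequency shifts toward fixation in a target group) and
#' autozygous runs (one sample's second haplotype overwritten by its first
#' over an interval). Everything downstream of the seed is deterministic.
#'
#' @param n_pops number of populations.
#' @param n_diploids_per_pop diploid samples per population.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param n_snps_per_chrom SNP count per chromosome (positions drawn
#'   uniformly without replacement, then sorted).
#' @param bn_F Balding-Nichols divergence parameter in `[0, 1)`; `0` means
#'   all populations share the ancestral frequency exactly.
#' @param freq_low,freq_high bounds of the uniform ancestral-frequency draw.
#' @param n_founders founder haplotypes per population (LD control);
#'   `Inf` draws haplotypes site-wise i.i.d. Bernoulli (no LD).
#' @param switch_rate per-bp founder-switch probability of the mosaic copy
#'   process (LD control); `Inf` resamples the founder at every site.
#' @param sweeps data frame (chrom, start, end, target_group, severity) of
#'   sweep intervals; severity `s` in `[0, 1]` moves the target group's
#'   frequencies to `(1 - s) p + s round(p)` before haplotypes are drawn
#'   (`s = 1` fixes the interval).
#' @param roh data frame (sample, chrom, start, end) of autozygous runs to
#'   plant after haplotype generation.
#' @param inbreeding_fis within-individual allele correlation in `[0, 1)`;
#'   scalar or one value per population. At each site, with this
#'   probability an individual's second allele is a copy of its first.
#' @param pop_names optional population labels; default `native1, ...,
#'   commercial1` with the last population commercial (a many-native /
#'   one-commercial design unless `n_pops == 2`, which gives one of each).
#' @param supersets optional per-population superset labels
#'   (`native`/`commercial`).
#' @param seed integer seed; all generator randomness derives from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_pops = 2, n_diploids_per_pop = 20, n_chroms = 1,
                       chrom_length = 5e6, n_snps_per_chrom = 5000,
                       bn_F = 0.2, freq_low = 0.05, freq_high = 0.95,
                       n_founders = 40, switch_rate = 2e-5,
                       sweeps = NULL, roh = NULL, inbreeding_fis = 0,
                       pop_names = NULL, supersets = NULL, seed = 1) {
  cfg <- list(n_pops = as.integer(n_pops),
              n_diploids_per_pop = as.integer(n_diploids_per_pop),
              n_chroms = as.integer(n_chroms),
              chrom_length = as.numeric(chrom_length),
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              bn_F = bn_F, freq_low = freq_low, freq_high = freq_high,
              n_founders = n_founders, switch_rate = switch_rate,
              sweeps = sweeps, roh = roh,
              inbreeding_fis = inbreeding_fis,
              pop_names = pop_names, supersets = supersets,
              seed = as.integer(seed))
  for (f in c("n_pops", "n_diploids_per_pop", "n_chroms", "chrom_length",
              "n_snps_per_chrom"))
    if (is.na(cfg[[f]]) || cfg[[f]] <= 0) stop("invalid config: ", f, " must be positive")
  if (cfg$n_snps_per_chrom > cfg$chrom_length)
    stop("invalid config: n_snps_per_chrom exceeds chrom_length")
  if (cfg$bn_F < 0 || cfg$bn_F >= 1)
    stop("invalid config: bn_F must be in [0, 1)")
  if (cfg$freq_low <= 0 || cfg$freq_high >= 1 || cfg$freq_low >= cfg$freq_high)
    stop("invalid config: need 0 < freq_low < freq_high < 1")
  if (any(cfg$inbreeding_fis < 0) || any(cfg$inbreeding_fis >= 1))
    stop("invalid config: inbreeding_fis must be in [0, 1)")
  if (!length(cfg$inbreeding_fis) %in% c(1L, cfg$n_pops))
    stop("invalid config: inbreeding_fis must be scalar or one per population")
  if (is.null(cfg$supersets)) {
    cfg$supersets <- if (cfg$n_pops == 1L) "native" else
      c(rep("native", cfg$n_pops - 1L), "commercial")
  }
  if (!all(cfg$supersets %in% c("native", "commercial")))
    stop("invalid config: supersets must be 'native' or 'commercial'")
  if (is.null(cfg$pop_names)) {
    cfg$pop_names <- stats::ave(cfg$supersets, cfg$supersets,
                                FUN = function(x) paste0(x, seq_along(x)))
  }
  if (length(cfg$pop_names) != cfg$n_pops || length(cfg$supersets) != cfg$n_pops)
    stop("invalid config: pop_names/supersets must have one entry per population")
  if (!is.null(cfg$sweeps)) {
    sw <- cfg$sweeps
    stopifnot(all(c("chrom", "start", "end", "target_group", "severity") %in% names(sw)))
    if (any(sw$severity < 0 | sw$severity > 1))
      stop("invalid config: sweep severity must be in [0, 1]")
    if (any(sw$start < 1 | sw$end > cfg$chrom_length | sw$start > sw$end))
      stop("invalid config: sweep interval outside chromosome bounds")
  }
  if (!is.null(cfg$roh)) {
    stopifnot(all(c("sample", "chrom", "start", "end") %in% names(cfg$roh)))
    if (any(cfg$roh$start < 1 | cfg$roh$end > cfg$chrom_length))
      stop("invalid config: roh interval outside chromosome bounds")
  }
  structure(cfg, class = "sim_config")
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

#' Draw ancestral and per-population allele frequencies
#'
#' Ancestral frequency `p ~ Uniform(freq_low, freq_high)` per site; each
#' population then draws `Beta(p(1-F)/F, (1-p)(1-F)/F)` independently
#' (variance `F p (1-p)`), or shares `p` exactly when `F = 0`.
#'
#' @param cfg a [sim_config()].
#' @return A `sim_freqs` list: chrom, pos, `p_anc`, and `p_pop`
#'   (sites x populations matrix).
#' @export
draw_frequencies <- function(cfg) {
  set.seed(cfg$seed)
  chroms <- sim_chrom_names(cfg)
  pos <- chrom <- list()
  for (ch in chroms) {
    pos[[ch]] <- sort(sample.int(cfg$chrom_length, cfg$n_snps_per_chrom))
    chrom[[ch]] <- rep(ch, cfg$n_snps_per_chrom)
  }
  pos <- unlist(pos, use.names = FALSE)
  chrom <- unlist(chrom, use.names = FALSE)
  S <- length(pos)
  p_anc <- stats::runif(S, cfg$freq_low, cfg$freq_high)
  p_pop <- matrix(NA_real_, S, cfg$n_pops,
                  dimnames = list(NULL, cfg$pop_names))
  if (cfg$bn_F == 0) {
    p_pop[] <- p_anc
  } else {
    f <- (1 - cfg$bn_F) / cfg$bn_F
    for (k in seq_len(cfg$n_pops))
      p_pop[, k] <- stats::rbeta(S, p_anc * f, (1 - p_anc) * f)
  }
  structure(list(chrom = chrom, pos = as.integer(pos),
                 p_anc = p_anc, p_pop = p_pop),
            class = "sim_freqs")
}

#' Plant sweeps into drawn frequencies
#'
#' Within each sweep interval, the target group's per-site frequencies `p`
#' are pulled toward the nearest boundary: `p' = (1 - s) p + s [p >= 0.5]`.
#' Severity 1 fixes the interval (zero diversity in the target group);
#' severity 0 leaves the panel unchanged.
#'
#' @param freqs a `sim_freqs` from [draw_frequencies()].
#' @param cfg the [sim_config()] whose `sweeps` to apply.
#' @return Modified `sim_freqs`.
#' @export
plant_sweeps <- function(freqs, cfg) {
  sw <- cfg$sweeps
  if (is.null(sw) || nrow(sw) == 0L) return(freqs)
  targets <- lapply(seq_len(nrow(sw)), function(i) {
    hit <- cfg$pop_names == sw$target_group[i] | cfg$supersets == sw$target_group[i]
    if (!any(hit)) stop("sweep target_group '", sw$target_group[i],
                        "' matches no population")
    which(hit)
  })
  if (nrow(sw) > 1L) {
    for (i in seq_len(nrow(sw) - 1L)) for (j in seq((i + 1L), nrow(sw))) {
      if (sw$chrom[i] == sw$chrom[j] &&
          sw$start[i] <= sw$end[j] && sw$start[j] <= sw$end[i] &&
          length(intersect(targets[[i]], targets[[j]])))
        stop("overlapping sweeps on the same group and interval (rows ",
             i, " and ", j, ")")
    }
  }
  for (i in seq_len(nrow(sw))) {
    idx <- which(freqs$chrom == sw$chrom[i] &
                 freqs$pos >= sw$start[i] & freqs$pos <= sw$end[i])
    s <- sw$severity[i]
    for (k in targets[[i]]) {
      p <- freqs$p_pop[idx, k]
      freqs$p_pop[idx, k] <- (1 - s) * p + s * as.numeric(p >= 0.5)
    }
  }
  freqs
}

#' Generate a phased haplotype panel from per-population frequencies
#'
#' Per population, `n_founders` founder haplotypes are drawn site-wise
#' Bernoulli at the population frequency; each sample haplotype copies a
#' founder mosaic, resampling its founder at each site with probability
#' `1 - exp(-switch_rate * delta_bp)`. Two haplotypes form a diploid; at
#' each site, with probability `inbreeding_fis` the second allele is
#' replaced by a copy of the first, generating autozygosity.
#'
#' @param freqs a `sim_freqs` (after any sweep planting).
#' @param cfg the [sim_config()].
#' @return A `sim_panel` list: chrom, pos, `a1`, `a2` (sites x samples),
#'   sample ids and a `pop_map`.
#' @export
generate_haplotypes <- function(freqs, cfg) {
  set.seed(cfg$seed + 1L)
  S <- length(freqs$pos)
  n_dip <- cfg$n_diploids_per_pop
  n_tot <- n_dip * cfg$n_pops
  a1 <- matrix(NA_integer_, S, n_tot)
  a2 <- matrix(NA_integer_, S, n_tot)
  ids <- character(n_tot)
  fis <- rep(cfg$inbreeding_fis, length.out = cfg$n_pops)
  # per-chromosome switch probabilities between consecutive sites
  q <- numeric(S); q[] <- 1
  for (ch in unique(freqs$chrom)) {
    ii <- which(freqs$chrom == ch)
    if (length(ii) > 1L) {
      d <- diff(freqs$pos[ii])
      q[ii[-1L]] <- if (is.infinite(cfg$switch_rate)) 1 else
        1 - exp(-cfg$switch_rate * d)
    }
    q[ii[1L]] <- 1  # new chromosome: fresh founder
  }
  draw_hap <- function(p, founders) {
    if (is.null(founders)) return(stats::rbinom(S, 1L, p))
    sw <- stats::runif(S) < q
    seg <- cumsum(sw)
    fid <- sample.int(ncol(founders), max(seg), replace = TRUE)
    founders[cbind(seq_len(S), fid[seg])]
  }
  for (k in seq_len(cfg$n_pops)) {
    p <- freqs$p_pop[, k]
    founders <- if (is.finite(cfg$n_founders)) {
      matrix(stats::rbinom(S * cfg$n_founders, 1L, rep(p, cfg$n_founders)),
             S, cfg$n_founders)
    } else NULL
    for (i in seq_len(n_dip)) {
      col <- (k - 1L) * n_dip + i
      h1 <- draw_hap(p, founders)
      h2 <- draw_hap(p, founders)
      if (fis[k] > 0) {
        cp <- stats::runif(S) < fis[k]
        h2[cp] <- h1[cp]
      }
      a1[, col] <- h1; a2[, col] <- h2
      ids[col] <- sprintf("%s_%02d", cfg$pop_names[k], i)
    }
  }
  pm <- pop_map(data.frame(sample = ids,
                           group = rep(cfg$pop_names, each = n_dip),
                           superset = rep(cfg$supersets, each = n_dip),
                           stringsAsFactors = FALSE))
  structure(list(chrom = freqs$chrom, pos = freqs$pos,
                 a1 = a1, a2 = a2, sample_ids = ids, popmap = pm),
            class = "sim_panel")
}

#' Plant autozygous runs into a haplotype panel
#'
#' For each requested interval, the named sample's second haplotype is
#' overwritten with its first, making the sample homozygous at every SNP
#' inside the interval.
#'
#' @param panel a `sim_panel`.
#' @param roh data frame (sample, chrom, start, end); `NULL` is a no-op.
#' @return Modified `sim_panel`.
#' @export
plant_roh <- function(panel, roh) {
  if (is.null(roh) || nrow(roh) == 0L) return(panel)
  for (i in seq_len(nrow(roh))) {
    s <- match(roh$sample[i], panel$sample_ids)
    if (is.na(s)) stop("unknown sample in roh plant: ", roh$sample[i])
    idx <- which(panel$chrom == roh$chrom[i] &
                 panel$pos >= roh$start[i] & panel$pos <= roh$end[i])
    panel$a2[idx, s] <- panel$a1[idx, s]
  }
  panel
}

#' Simulate a complete structured-population SNP panel
#'
#' Runs frequency drawing, sweep planting, haplotype generation and
#' autozygosity planting, and packages the result as a phased
#' [geno_matrix()] plus population map and ground truth.
#'
#' @param cfg a [sim_config()].
#' @return A list: `gm` (phased [geno_matrix()]), `popmap` (`pop_map`),
#'   `truth` (`sim_truth`: post-sweep per-population frequencies, sweep and
#'   roh interval tables, seed, config).
#' @export
simulate_panel <- function(cfg) {
  freqs <- draw_frequencies(cfg)
  freqs <- plant_sweeps(freqs, cfg)
  panel <- generate_haplotypes(freqs, cfg)
  panel <- plant_roh(panel, cfg$roh)
  S <- length(panel$pos)
  gm <- geno_matrix(
    chrom = panel$chrom, pos = panel$pos,
    ref = rep("A", S), alt = rep("C", S),
    a1 = panel$a1, a2 = panel$a2, phased = TRUE,
    sample_ids = panel$sample_ids,
    contig_lengths = stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                                     sim_chrom_names(cfg)))
  truth <- structure(list(chrom = panel$chrom, pos = panel$pos,
                          p_anc = freqs$p_anc, p_pop = freqs$p_pop,
                          sweeps = cfg$sweeps, roh = cfg$roh,
                          seed = cfg$seed, config = cfg),
                     class = "sim_truth")
  list(gm = gm, popmap = panel$popmap, truth = truth)
}

#' Write a simulated panel to disk
#'
#' Emits `panel.vcf` (phased VCF v4.2 with contig headers), `popmap.tsv`,
#' `sweeps.bed` and `roh.bed` (0-based half-open truth intervals) and
#' `config.txt` (YAML key-value echo). Outputs are byte-identical across
#' reruns with the same config and seed.
#'
#' @param sim result of [simulate_panel()].
#' @param outdir output directory (created if absent).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sim <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(outdir, "panel.vcf"),
             popmap = file.path(outdir, "popmap.tsv"),
             sweeps = file.path(outdir, "sweeps.bed"),
             roh = file.path(outdir, "roh.bed"),
             config = file.path(outdir, "config.txt"))
  write_vcf(sim$gm, paths[["vcf"]])
  utils::write.table(sim$popmap, paths[["popmap"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bed(sim$truth$sweeps, paths[["sweeps"]],
            name_col = "target_group", score_col = "severity")
  write_bed(sim$truth$roh, paths[["roh"]], name_col = "sample")
  cfg <- unclass(sim$truth$config)
  cfg$sweeps <- if (is.null(cfg$sweeps)) NULL else as.list(cfg$sweeps)
  cfg$roh <- if (is.null(cfg$roh)) NULL else as.list(cfg$roh)
  writeLines(yaml::as.yaml(cfg), paths[["config"]])
  invisible(paths)
}

# intervals: 1-based inclusive in, BED 0-based half-open out
write_bed <- function(df, path, name_col = NULL, score_col = NULL) {
  if (is.null(df) || nrow(df) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end)
  if (!is.null(name_col)) out$name <- df[[name_col]]
  if (!is.null(score_col)) out$score <- df[[score_col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
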