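# ---- pipeline orchestration: simulate / filter / statistics / scan ----
# Each run_* function is a thin, deterministic wrapper over the package's
# analysis functions: it reads standard inputs (VCF, popmap TSV, gene BED
# or already-loaded objects), applies the post-calling site filters, and
# writes TSV/BED outputs whose headers echo the resolved configuration as
# "#key=value" lines, so mixed-configuration output directories are
# detectable and every run is reproducible from its own files.

as_gm <- function(x) if (inherits(x, "geno_matrix")) x else read_vcf(x)
as_pm <- function(x) if (inherits(x, "pop_map")) x else read_popmap(x)

provenance_lines <- function(params) {
  flat <- unlist(params)
  c("#popgenscan", sprintf("#%s=%s", names(flat), as.character(flat)))
}

write_tsv <- function(df, path, params = list()) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(provenance_lines(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

apply_site_filters <- function(gm, gq_min, mq_min, cluster_max, cluster_span) {
  fq <- filter_quality(gm, gq_min = gq_min, mq_min = mq_min)
  fc <- filter_biallelic_and_clusters(fq$gm, max_in_span = cluster_max,
                                      span = cluster_span)
  list(gm = fc$gm, counts = c(fq$counts, fc$counts))
}

#' Simulate a panel and write it to a fixture directory
#'
#' @param cfg a [sim_config()] or path to a YAML file of its fields.
#' @param outdir output directory.
#' @return Named paths of the written files, invisibly.
#' @export
run_simulate <- function(cfg, outdir) {
  if (is.character(cfg)) {
    fields <- yaml::read_yaml(cfg)
    for (f in c("sweeps", "roh"))
      if (!is.null(fields[[f]])) fields[[f]] <- as.data.frame(fields[[f]])
    cfg <- do.call(sim_config, fields)
  }
  write_sim(simulate_panel(cfg), outdir)
}

#' Two-statistic selective-sweep scan
#'
#' Runs the full scan: site filters, sliding windows, windowed nucleotide
#' diversity for both contrast groups, windowed weighted F_ST, the log2
#' diversity ratio, empirical-quantile outliers, region merging and
#' intersection, and gene annotation. Writes `windows.tsv`,
#' `thresholds.tsv`, `regions_{fst,ratio,intersection}.bed`,
#' `candidate_genes.tsv` and `scan_log.txt` into `outdir`.
#'
#' @param vcf VCF path or [geno_matrix()].
#' @param popmap popmap TSV path or `pop_map`.
#' @param outdir output directory.
#' @param genes optional gene BED path or 1-based gene data frame.
#' @param contrast length-2 character: group or superset labels
#'   (numerator, denominator of the diversity ratio).
#' @param window_size,window_step sliding-window scheme in bp.
#' @param fst_frac,ratio_frac,ratio_tail outlier settings
#'   (see [call_candidate_regions()]).
#' @param gq_min,mq_min,cluster_max,cluster_span site-filter settings.
#' @return Invisibly, a list with the window table, the `sweep_report`,
#'   the annotation tables, the genome-wide F_ST and filter counts.
#' @export
run_scan <- function(vcf, popmap, outdir, genes = NULL,
                     contrast = c("native", "commercial"),
                     window_size = 50000, window_step = 25000,
                     fst_frac = 0.05, ratio_frac = 0.01,
                     ratio_tail = "upper",
                     gq_min = 40, mq_min = 25,
                     cluster_max = 3, cluster_span = 10) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- as_gm(vcf); pm <- as_pm(popmap)
  for (g in contrast) resolve_samples(pm, g)  # fail before computation
  flt <- apply_site_filters(gm, gq_min, mq_min, cluster_max, cluster_span)
  gm <- flt$gm
  params <- list(contrast_a = contrast[1], contrast_b = contrast[2],
                 window_size = window_size, window_step = window_step,
                 fst_frac = fst_frac, ratio_frac = ratio_frac,
                 ratio_tail = ratio_tail, gq_min = gq_min, mq_min = mq_min,
                 cluster_max = cluster_max, cluster_span = cluster_span)
  wins <- make_windows(contig_lengths(gm), window_size, window_step)
  fst <- windowed_weighted_fst(gm, pm, contrast[1], contrast[2], wins)
  pi_a <- windowed_pi(gm, pm, contrast[1], wins)
  pi_b <- windowed_pi(gm, pm, contrast[2], wins)
  ratio <- log2_pi_ratio(pi_a, pi_b)
  report <- call_candidate_regions(fst$windows, ratio, fst_frac, ratio_frac,
                                   ratio_tail)
  gene_df <- if (is.null(genes)) NULL
             else if (is.character(genes)) read_genes_bed(genes) else genes
  ann <- annotate_regions(report, gene_df)

  tab <- cbind(fst$windows[, c("chrom", "start", "end", "index", "truncated",
                               "n_sites_fst", "fst", "no_usable_sites")],
               ratio[, c("pi_a", "pi_b", "log2_ratio", "zero_pi")])
  tab$fst_outlier <- tab$index %in% report$outlier_windows$fst
  tab$ratio_outlier <- tab$index %in% report$outlier_windows$ratio
  write_tsv(tab, file.path(outdir, "windows.tsv"), params)
  write_tsv(data.frame(statistic = names(report$thresholds),
                       threshold = unname(report$thresholds),
                       tail_frac = c(fst_frac, ratio_frac),
                       k_flagged = unname(report$counts[c("k_fst", "k_ratio")]),
                       n_usable = unname(report$counts[
                         c("n_windows_fst_usable", "n_windows_ratio_usable")])),
            file.path(outdir, "thresholds.tsv"), params)
  write_bed(report$regions_fst, file.path(outdir, "regions_fst.bed"))
  write_bed(report$regions_ratio, file.path(outdir, "regions_ratio.bed"))
  write_bed(report$regions_intersection,
            file.path(outdir, "regions_intersection.bed"))
  write_tsv(if (nrow(ann$genes)) ann$genes else
              data.frame(gene = character(0), chrom = character(0),
                         gene_start = numeric(0), gene_end = numeric(0),
                         region_ids = character(0), statistics = character(0),
                         overlap_bp = numeric(0)),
            file.path(outdir, "candidate_genes.tsv"), params)
  log_lines <- c(provenance_lines(params),
                 sprintf("filter.%s=%d", names(flt$counts), flt$counts),
                 sprintf("scan.%s=%s", names(report$counts), report$counts),
                 sprintf("scan.genome_fst=%.6f", fst$genome_fst),
                 sprintf("scan.n_sites_usable=%d", fst$n_sites_usable),
                 sprintf("scan.n_sites_skipped=%d", fst$n_sites_skipped))
  writeLines(log_lines, file.path(outdir, "scan_log.txt"))
  invisible(list(windows = tab, report = report, annotation = ann,
                 genome_fst = fst$genome_fst, filter_counts = flt$counts))
}

#' Per-group diversity tables
#'
#' Writes `diversity_summary.tsv` (Ho, He, Pn, F_mean per group),
#' `inbreeding_f.tsv` (per sample) and `pi_windows.tsv` (windowed
#' nucleotide diversity, one block per group).
#'
#' @inheritParams run_scan
#' @return Invisibly, the three tables.
#' @export
run_diversity <- function(vcf, popmap, outdir,
                          window_size = 50000, window_step = 25000,
                          gq_min = 40, mq_min = 25,
                          cluster_max = 3, cluster_span = 10) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- as_gm(vcf); pm <- as_pm(popmap)
  flt <- apply_site_filters(gm, gq_min, mq_min, cluster_max, cluster_span)
  gm <- flt$gm
  params <- list(window_size = window_size, window_step = window_step,
                 gq_min = gq_min, mq_min = mq_min)
  summ <- diversity_summary(gm, pm)
  fin <- inbreeding_f(gm, pm)
  wins <- make_windows(contig_lengths(gm), window_size, window_step)
  pis <- do.call(rbind, lapply(unique(pm$group), function(g)
    windowed_pi(gm, pm, g, wins)))
  write_tsv(summ, file.path(outdir, "diversity_summary.tsv"), params)
  write_tsv(fin$per_sample, file.path(outdir, "inbreeding_f.tsv"), params)
  write_tsv(pis, file.path(outdir, "pi_windows.tsv"), params)
  invisible(list(summary = summ, inbreeding = fin, pi_windows = pis))
}

#' LD-decay table
#'
#' @inheritParams run_scan
#' @inheritParams ld_decay
#' @return Invisibly, the decay table (also written as `ld_decay.tsv`).
#' @export
run_ld_decay <- function(vcf, popmap = NULL, outdir, group = NULL,
                         bin_edges_kb = c(0, 1, 3, 5, 15, 60, 100),
                         mode = "dosage", max_pairs_per_bin = 10000,
                         seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- as_gm(vcf)
  pm <- if (!is.null(popmap)) as_pm(popmap) else NULL
  tab <- ld_decay(gm, pm, group, bin_edges_kb, mode, max_pairs_per_bin, seed)
  out <- if (is.null(group)) cbind(group = "all", tab) else cbind(group = group, tab)
  write_tsv(out, file.path(outdir, "ld_decay.tsv"),
            list(group = if (is.null(group)) "all" else group, mode = mode,
                 max_pairs_per_bin = max_pairs_per_bin, seed = seed))
  invisible(out)
}

#' LD pruning: surviving site list
#'
#' @inheritParams run_scan
#' @inheritParams ld_prune
#' @return Invisibly, the kept-site table (written as `pruned_sites.tsv`).
#' @export
run_prune <- function(vcf, outdir, window_snps = 50, step_snps = 10,
                      r2_max = 0.1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- as_gm(vcf)
  pr <- ld_prune(gm, window_snps = window_snps, step_snps = step_snps,
                 r2_max = r2_max)
  out <- data.frame(chrom = gm$chrom[pr$keep], pos = gm$pos[pr$keep])
  write_tsv(out, file.path(outdir, "pruned_sites.tsv"),
            list(window_snps = window_snps, step_snps = step_snps,
                 r2_max = r2_max, n_in = n_sites(gm), n_kept = length(pr$keep)))
  invisible(list(sites = out, prune = pr))
}

#' ROH detection tables
#'
#' Writes `roh.tsv`, `roh.bed` (0-based half-open) and `roh_summary.tsv`.
#'
#' @inheritParams run_scan
#' @inheritParams detect_roh
#' @return Invisibly, segments and summaries.
#' @export
run_roh <- function(vcf, popmap, outdir, min_kb = 100, min_snps = 50,
                    scan_window_snps = 50, max_het_per_window = 1,
                    max_miss_per_window = 5, hit_frac = 0.05) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- as_gm(vcf); pm <- as_pm(popmap)
  segs <- detect_roh(gm, pm$sample[pm$sample %in% gm$sample_ids],
                     min_kb, min_snps, scan_window_snps,
                     max_het_per_window, max_miss_per_window, hit_frac)
  summ <- roh_summary(segs, pm)
  params <- list(min_kb = min_kb, min_snps = min_snps,
                 scan_window_snps = scan_window_snps,
                 max_het_per_window = max_het_per_window,
                 max_miss_per_window = max_miss_per_window,
                 hit_frac = hit_frac)
  write_tsv(segs, file.path(outdir, "roh.tsv"), params)
  if (nrow(segs)) write_bed(segs, file.path(outdir, "roh.bed"),
                            name_col = "sample")
  else writeLines(character(0), file.path(outdir, "roh.bed"))
  write_tsv(summ$per_group, file.path(outdir, "roh_summary.tsv"), params)
  invisible(list(segments = segs, summary = summ))
}

#' GRM and principal components
#'
#' Optionally LD-prunes, builds the relationship matrix and its principal
#' components. Writes `grm.tsv` (square), `grm_sparse.tsv` (3-column
#' lower triangle), `pca_coords.tsv` and `scree.tsv`.
#'
#' @inheritParams run_scan
#' @param k number of components.
#' @param prune apply [ld_prune()] (50/10/0.1) before the GRM.
#' @return Invisibly, the `grm_matrix` and PCA result.
#' @export
run_pca <- function(vcf, popmap, outdir, k = 2, prune = TRUE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gm <- as_gm(vcf); pm <- as_pm(popmap)
  if (prune) gm <- gm_subset(gm, sites = ld_prune(gm)$keep)
  rm_ <- grm(gm)
  pc <- pca_grm(rm_, k)
  params <- list(k = k, prune = prune, n_sites_used = rm_$n_sites_used)
  sq <- data.frame(sample = rm_$sample_ids, rm_$values, check.names = FALSE)
  write_tsv(sq, file.path(outdir, "grm.tsv"), params)
  lt <- which(lower.tri(rm_$values, diag = TRUE), arr.ind = TRUE)
  write_tsv(data.frame(sample_i = rm_$sample_ids[lt[, 1]],
                       sample_j = rm_$sample_ids[lt[, 2]],
                       value = rm_$values[lt]),
            file.path(outdir, "grm_sparse.tsv"), params)
  coords <- merge(pc$coords, pm[, c("sample", "group")], by = "sample",
                  all.x = TRUE, sort = FALSE)
  write_tsv(coords, file.path(outdir, "pca_coords.tsv"), params)
  write_tsv(data.frame(component = seq_along(pc$eigenvalues),
                       eigenvalue = pc$eigenvalues),
            file.path(outdir, "scree.tsv"), params)
  invisible(list(grm = rm_, pca = pc))
}
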