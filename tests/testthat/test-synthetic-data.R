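test_that("frequency draws follow the Balding-Nichols variance identity", {
  # F = 0: every population shares the ancestral frequency exactly
  cfg0 <- sim_config(bn_F = 0, n_snps_per_chrom = 200, seed = 3)
  fr0 <- draw_frequencies(cfg0)
  expect_equal(fr0$p_pop[, 1], fr0$p_anc)
  expect_equal(fr0$p_pop[, 2], fr0$p_anc)
  # F = 0.2: mean_site Var(p_pop) / (p_anc (1 - p_anc)) ~ 0.2
  cfg <- sim_config(n_pops = 10, n_snps_per_chrom = 20000,
                    chrom_length = 2e7, bn_F = 0.2, seed = 5)
  fr <- draw_frequencies(cfg)
  ratio <- apply(fr$p_pop, 1, stats::var) / (fr$p_anc * (1 - fr$p_anc))
  expect_lt(abs(mean(ratio) - 0.2), 0.02)
  # same seed -> identical arrays; F = 1 rejected
  fr2 <- draw_frequencies(cfg)
  expect_identical(fr$p_pop, fr2$p_pop)
  expect_error(sim_config(bn_F = 1), "bn_F")
})

test_that("founder-mosaic haplotypes give flat r2 when switching every site and decay when not", {
  base <- list(n_pops = 1, n_diploids_per_pop = 50, n_snps_per_chrom = 8000,
               chrom_length = 4e6, n_founders = 8, bn_F = 0.05,
               freq_low = 0.1, freq_high = 0.9, seed = 5)
  ind <- simulate_panel(do.call(sim_config, c(base, switch_rate = Inf)))
  d_ind <- ld_decay(ind$gm, max_pairs_per_bin = 5000, seed = 2)
  expect_lt(max(d_ind$mean_r2) - min(d_ind$mean_r2), 0.01)
  n_hap <- 2 * 50
  expect_lt(mean(d_ind$mean_r2), 4 / n_hap)  # near the finite-sample null
  mos <- simulate_panel(do.call(sim_config, c(base, switch_rate = 3e-5)))
  d_mos <- ld_decay(mos$gm, max_pairs_per_bin = 5000, seed = 2)
  expect_true(all(diff(d_mos$mean_r2) < 0))
})

test_that("per-site heterozygosity matches the expectation of the realized frequencies", {
  cfg <- sim_config(n_pops = 1, n_diploids_per_pop = 60,
                    n_snps_per_chrom = 4000, chrom_length = 4e6,
                    n_founders = Inf, seed = 13)
  sim <- simulate_panel(cfg)
  p <- sim$truth$p_pop[, 1]
  d <- dosage(sim$gm)
  ho <- rowMeans(d == 1L)
  expected <- mean(2 * p * (1 - p))
  se <- stats::sd(2 * p * (1 - p)) / sqrt(length(p))  # Monte-Carlo SE
  expect_lt(abs(mean(ho) - expected), 2 * se + 3 * sqrt(0.5 / (60 * length(p))))
})

test_that("full inbreeding makes every individual homozygous", {
  cfg <- sim_config(n_pops = 1, n_diploids_per_pop = 5,
                    n_snps_per_chrom = 300, chrom_length = 1e5,
                    inbreeding_fis = 0.999999, seed = 2)
  sim <- simulate_panel(cfg)
  expect_true(all(dosage(sim$gm) != 1L))
})

test_that("sweep planting fixes or preserves target-group frequencies as severity dictates", {
  sw <- data.frame(chrom = "chr1", start = 2e6, end = 2.5e6,
                   target_group = "commercial", severity = 1)
  cfg <- sim_config(sweeps = sw, seed = 21)
  sim <- simulate_panel(cfg)
  inside <- sim$truth$pos >= 2e6 & sim$truth$pos <= 2.5e6
  expect_true(all(sim$truth$p_pop[inside, "commercial1"] %in% c(0, 1)))
  # target group monomorphic over the interval -> windowed pi is zero there
  w <- make_windows(contig_lengths(sim$gm))
  piw <- windowed_pi(sim$gm, sim$popmap, "commercial", w)
  fully <- piw$start >= 2e6 & piw$end <= 2.5e6
  expect_true(all(piw$pi[fully] == 0))
  # and the log2 ratio is flagged degenerate in those windows
  pin <- windowed_pi(sim$gm, sim$popmap, "native", w)
  lr <- log2_pi_ratio(pin, piw)
  expect_true(all(lr$zero_pi[fully]))
  # severity 0 leaves the panel unchanged
  sw0 <- transform(sw, severity = 0)
  cfg0 <- sim_config(sweeps = sw0, seed = 21)
  cfg_none <- sim_config(seed = 21)
  expect_identical(simulate_panel(cfg0)$gm$a1, simulate_panel(cfg_none)$gm$a1)
  # overlapping sweeps on the same group are rejected
  sw2 <- rbind(sw, transform(sw, start = 2.3e6, end = 2.8e6))
  expect_error(simulate_panel(sim_config(sweeps = sw2, seed = 21)), "verlap")
})

test_that("roh planting makes the named sample homozygous inside the interval", {
  roh <- data.frame(sample = c("native1_01", "native1_01"), chrom = "chr1",
                    start = c(1e6, 3e6), end = c(1.6e6, 3.4e6))
  cfg <- sim_config(roh = roh, seed = 4)
  sim <- simulate_panel(cfg)
  d <- dosage(sim$gm)[, "native1_01"]
  for (i in 1:2) {
    inside <- sim$gm$pos >= roh$start[i] & sim$gm$pos <= roh$end[i]
    expect_true(all(d[inside] != 1L), label = paste("plant", i))
  }
  # an interval containing no SNPs is a no-op but stays in the truth table
  cfg2 <- sim_config(n_snps_per_chrom = 10, chrom_length = 1e6,
                     roh = data.frame(sample = "native1_01", chrom = "chr1",
                                      start = 999990, end = 999999), seed = 4)
  sim2 <- simulate_panel(cfg2)
  expect_equal(nrow(sim2$truth$roh), 1L)
  expect_error(simulate_panel(sim_config(
    roh = data.frame(sample = "nobody", chrom = "chr1", start = 1, end = 10),
    seed = 1)), "unknown sample")
})

test_that("emitted fixture directories are complete and byte-identical across reruns", {
  cfg <- sim_config(seed = 7)
  sim <- simulate_panel(cfg)
  expect_equal(n_sites(sim$gm), 5000L)
  expect_equal(n_samples(sim$gm), 40L)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  write_sim(sim, d1)
  write_sim(simulate_panel(cfg), d2)
  expect_setequal(list.files(d1), c("panel.vcf", "popmap.tsv", "sweeps.bed",
                                    "roh.bed", "config.txt"))
  expect_true(files_byte_identical(d1, d2))
  pm <- read_popmap(file.path(d1, "popmap.tsv"))
  expect_equal(sort(pm$sample), sort(sim$gm$sample_ids))
  expect_equal(anyDuplicated(pm$sample), 0L)
  # and the VCF round-trips through the reader
  gm2 <- read_vcf(file.path(d1, "panel.vcf"))
  expect_true(gm_identical(sim$gm, gm2))
})
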