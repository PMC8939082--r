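test_that("Weir-Cockerham components match hand-derived values to 1e-12", {
  # fixed difference: pop1 {AA,AA} vs pop2 {aa,aa}
  e1 <- wc_site_components(n = c(2, 2), p = c(0, 1), h = c(0, 0))
  expect_equal(c(e1$a, e1$b, e1$c), c(0.5, 0, 0), tolerance = 1e-12)
  expect_equal(e1$a / (e1$a + e1$b + e1$c), 1, tolerance = 1e-12)
  # pop1 {AA,Aa} vs pop2 {aa,aa}
  e2 <- wc_site_components(n = c(2, 2), p = c(0.25, 1), h = c(0.5, 0))
  expect_equal(c(e2$a, e2$b, e2$c), c(0.25, 0, 0.125), tolerance = 1e-12)
  expect_equal(e2$a / (e2$a + e2$b + e2$c), 2 / 3, tolerance = 1e-12)
  # identical groups {AA,Aa}: negative site F_ST is allowed
  e3 <- wc_site_components(n = c(2, 2), p = c(0.25, 0.25), h = c(0.5, 0.5))
  expect_equal(c(e3$a, e3$b, e3$c), c(-0.0625, 0, 0.25), tolerance = 1e-12)
  expect_equal(e3$a / (e3$a + e3$b + e3$c), -1 / 3, tolerance = 1e-12)
})

test_that("components agree with an independent ANOVA evaluation on every two-diploid configuration", {
  genos <- expand.grid(g11 = 0:2, g12 = 0:2, g21 = 0:2, g22 = 0:2)
  for (i in seq_len(nrow(genos))) {
    g1 <- c(genos$g11[i], genos$g12[i])
    g2 <- c(genos$g21[i], genos$g22[i])
    oracle <- wc_anova_oracle(g1, g2)
    got <- wc_site_components(n = c(2, 2),
                              p = c(mean(g1) / 2, mean(g2) / 2),
                              h = c(mean(g1 == 1), mean(g2 == 1)))
    expect_equal(c(got$a, got$b, got$c), unname(oracle), tolerance = 1e-12,
                 label = paste("config", i))
  }
})

test_that("windowed weighted F_ST is the ratio of sums, with degenerate windows flagged", {
  # window containing exactly the {AA,Aa} vs {aa,aa} site -> fst = 2/3
  d <- matrix(c(0L, 1L, 2L, 2L), 1, 4)
  gm <- gm_from_dosage(d, pos = 100L, contig_len = 50000)
  pm <- pop_map(data.frame(sample = gm$sample_ids,
                           group = rep(c("p1", "p2"), each = 2),
                           superset = rep(c("native", "commercial"), each = 2)))
  w <- make_windows(c(chr1 = 50000))
  fst <- windowed_weighted_fst(gm, pm, "p1", "p2", w)
  expect_equal(fst$windows$fst[1], 2 / 3, tolerance = 1e-12)
  expect_equal(fst$genome_fst, 2 / 3, tolerance = 1e-12)
  # cross-group-monomorphic window flagged unusable
  gm0 <- gm_from_dosage(matrix(0L, 2, 4), pos = c(100L, 200L), contig_len = 50000)
  fst0 <- windowed_weighted_fst(gm0, pm, "p1", "p2", w)
  expect_true(all(fst0$windows$no_usable_sites))
  expect_true(all(is.na(fst0$windows$fst)))
  expect_error(windowed_weighted_fst(gm, pm, "p1", "p1", w), "differ")
  # ratio-of-sums lies within per-site ratio range when denominators positive
  set.seed(15)
  d2 <- matrix(rbinom(10 * 8, 2, rep(c(0.2, 0.8), each = 4 * 10)), 10, 8)
  gm2 <- gm_from_dosage(d2, pos = seq_len(10) * 100L, contig_len = 50000)
  pm2 <- pop_map(data.frame(sample = gm2$sample_ids,
                            group = rep(c("p1", "p2"), each = 4),
                            superset = rep(c("native", "commercial"), each = 4)))
  comp <- popgenscan:::wc_components_sites(
    popgenscan:::group_site_counts(gm2, pm2$sample[1:4]),
    popgenscan:::group_site_counts(gm2, pm2$sample[5:8]),
    n_alt_alleles(gm2))
  den <- comp$a + comp$b + comp$c
  if (all(den[comp$usable] > 0)) {
    ratios <- comp$a[comp$usable] / den[comp$usable]
    fst2 <- windowed_weighted_fst(gm2, pm2, "p1", "p2", w)
    expect_gte(fst2$windows$fst[1], min(ratios))
    expect_lte(fst2$windows$fst[1], max(ratios))
  }
})

test_that("genome-wide weighted F_ST recovers the Balding-Nichols divergence parameter", {
  for (target in c(0.05, 0.2)) {
    cfg <- sim_config(n_diploids_per_pop = 50, n_snps_per_chrom = 20000,
                      chrom_length = 2e7, bn_F = target, n_founders = Inf,
                      seed = 100 + round(1000 * target))
    sim <- simulate_panel(cfg)
    w <- make_windows(contig_lengths(sim$gm))
    fst <- windowed_weighted_fst(sim$gm, sim$popmap, "native", "commercial", w)
    expect_lt(abs(fst$genome_fst - target), 0.02, label = paste("bn_F", target))
  }
})

test_that("log2 pi ratio handles equal, doubled and degenerate diversities", {
  w <- make_windows(c(chr1 = 100000))
  mk <- function(pi) cbind(w, group = "g", n_snps = 1L, pi = pi)
  a <- mk(c(2e-5, 4e-5, 1e-5, 0))
  b <- mk(c(2e-5, 2e-5, 0, 1e-5))
  lr <- log2_pi_ratio(a, b)
  expect_equal(lr$log2_ratio[1], 0)
  expect_equal(lr$log2_ratio[2], 1)
  expect_true(lr$zero_pi[3] && lr$zero_pi[4])
  expect_true(all(is.na(lr$log2_ratio[3:4])))
  b_bad <- mk(1e-5)[c(2, 1, 3, 4), ]
  expect_error(log2_pi_ratio(a, b_bad), "match")
})

test_that("empirical outliers follow the nearest-rank convention with genomic tie-breaking", {
  v <- seq(0.01, 1, by = 0.01)
  o <- empirical_outliers(v, 0.05)
  expect_equal(o$k, 5L)
  expect_equal(sort(v[o$flagged]), c(0.96, 0.97, 0.98, 0.99, 1.00))
  expect_equal(o$threshold, 0.96)
  # N = 10, frac 0.05 -> ceiling gives k = 1, the maximum
  o2 <- empirical_outliers(seq(0.1, 1, by = 0.1), 0.05)
  expect_equal(o2$k, 1L)
  expect_equal(o2$flagged, 10L)
  # 10-way tie at the max: exactly 5 flagged, earliest windows first
  v3 <- c(rep(1, 10), seq(0.01, 0.90, by = 0.01))
  o3 <- empirical_outliers(v3, 0.05)
  expect_equal(o3$k, 5L)
  expect_equal(o3$flagged, 1:5)
  # all equal: first k in genomic order, with a warning
  expect_warning(o4 <- empirical_outliers(rep(0.5, 20), 0.1), "equal")
  expect_equal(o4$flagged, 1:2)
  # NA values are excluded from N
  o5 <- empirical_outliers(c(NA, v), 0.05)
  expect_equal(o5$n_usable, 100L)
  expect_equal(o5$k, 5L)
})

test_that("outlier windows merge into regions and intersect across statistics", {
  w <- make_windows(c(chr1 = 200000))  # 8 windows... 1..200k
  n <- nrow(w)
  fstw <- cbind(w, n_sites_fst = 1L, no_usable_sites = FALSE,
                fst = c(0.9, 0.8, rep(0.1, n - 2)))
  ratio <- cbind(w, pi_a = 1e-5, pi_b = 1e-5, zero_pi = FALSE,
                 log2_ratio = c(3, rep(0, n - 2), 2))
  rep_ <- call_candidate_regions(fstw, ratio, fst_frac = 0.25, ratio_frac = 0.25)
  # book-ended/overlapping fst windows 1-2 merge into one region
  expect_equal(nrow(rep_$regions_fst), 1L)
  expect_equal(rep_$regions_fst$start, 1)
  expect_equal(rep_$regions_fst$end, 75000)
  # ratio outliers are windows 1 and n -> two disjoint regions
  expect_equal(nrow(rep_$regions_ratio), 2L)
  # intersection covers only the shared span
  expect_equal(nrow(rep_$regions_intersection), 1L)
  expect_equal(rep_$regions_intersection$end, 50000)
  expect_equal(unname(rep_$counts["k_fst"]), ceiling(0.25 * n))
})

test_that("candidate regions pick up overlapping genes once, with region support listed", {
  regions <- list(
    regions_fst = data.frame(chrom = "chr1", start = 176340001, end = 176360000),
    regions_ratio = data.frame(chrom = "chr1", start = 176340001, end = 176360000),
    regions_intersection = data.frame(chrom = "chr1", start = 176340001,
                                      end = 176360000))
  rep_ <- structure(c(regions, list(thresholds = c(fst = 0.2, log2_ratio = 0.3),
                                    counts = c())), class = "sweep_report")
  genes <- data.frame(chrom = "chr1", start = 176330001, end = 176365000,
                      name = "HSPH1")
  ann <- annotate_regions(rep_, genes)
  expect_equal(nrow(ann$genes), 1L)
  expect_equal(ann$genes$gene, "HSPH1")
  expect_equal(ann$genes$statistics, "fst,intersection,log2_ratio")
  # no gene overlap -> empty gene table, regions reported with n_genes = 0
  ann0 <- annotate_regions(rep_, data.frame(chrom = "chr1", start = 1,
                                            end = 1000, name = "X"))
  expect_equal(nrow(ann0$genes), 0L)
  expect_true(all(ann0$regions$n_genes == 0L))
  # gene spanning two merged regions appears once with both ids
  rep2 <- rep_
  rep2$regions_fst <- data.frame(chrom = "chr1",
                                 start = c(176340001, 176380001),
                                 end = c(176360000, 176400000))
  gene2 <- data.frame(chrom = "chr1", start = 176350001, end = 176390000,
                      name = "WIDE")
  ann2 <- annotate_regions(rep2, gene2)
  expect_equal(nrow(ann2$genes), 1L)
  expect_equal(lengths(strsplit(ann2$genes$region_ids[ann2$genes$gene == "WIDE"],
                                ","))[[1]] >= 2, TRUE)
  # unannotated chromosome warns
  rep3 <- rep_
  rep3$regions_fst$chrom <- "chrUn"
  expect_warning(annotate_regions(rep3, genes), "chrUn")
})

test_that("the scan is invariant to sample ordering", {
  sw <- data.frame(chrom = "chr1", start = 2e6, end = 2.1e6,
                   target_group = "commercial", severity = 0.9)
  cfg <- sim_config(n_snps_per_chrom = 4000, chrom_length = 1e7,
                    sweeps = sw, n_founders = Inf, seed = 17)
  sim <- simulate_panel(cfg)
  w <- make_windows(contig_lengths(sim$gm))
  run1 <- windowed_weighted_fst(sim$gm, sim$popmap, "native", "commercial", w)
  perm <- sample(n_samples(sim$gm))
  gm_p <- gm_subset(sim$gm, samples = perm)
  pm_p <- sim$popmap[rev(seq_len(nrow(sim$popmap))), ]
  run2 <- windowed_weighted_fst(gm_p, pop_map(pm_p), "native", "commercial", w)
  expect_equal(run1$windows$fst, run2$windows$fst, tolerance = 1e-12)
  expect_equal(run1$genome_fst, run2$genome_fst, tolerance = 1e-12)
})
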