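test_that("VCF genotypes are read as dosages with missing and multiallelic handling", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=5000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tC\t.\t.\t.\tGT\t0/0\t0/1",
    "chr1\t200\t.\tG\tT\t.\t.\t.\tGT\t0|1\t1/1",
    "chr1\t300\t.\tA\tC\t.\t.\t.\tGT\t1/1\t./.",
    "chr1\t400\t.\tA\tC,T\t.\t.\t.\tGT\t0/2\t1/1"), f)
  gm <- read_vcf(f)
  expect_equal(n_sites(gm), 4L)
  expect_equal(gm$sample_ids, c("s1", "s2"))
  d <- dosage(gm)
  expect_equal(d[1, ], c(s1 = 0L, s2 = 1L))
  expect_equal(d[2, ], c(s1 = 1L, s2 = 2L))
  expect_true(is.na(d[3, "s2"]))           # ./. is missing
  expect_true(all(is.na(d[4, ])))          # multiallelic: dosage undefined
  expect_equal(n_alt_alleles(gm), c(1L, 1L, 1L, 2L))
  expect_true(gm$phased[2, 1] && !gm$phased[1, 1])
  expect_equal(unname(gm$contig_lengths["chr1"]), 5000)
})

test_that("VCF reader rejects duplicate samples and malformed records", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts1",
               "chr1\t5\t.\tA\tC\t.\t.\t.\tGT\t0/0\t0/1"), f)
  expect_error(read_vcf(f), "duplicate sample")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\tnotanumber\t.\tA\tC\t.\t.\t.\tGT\t0/0"), f)
  expect_error(read_vcf(f), "line 3")
})

test_that("write/read round trip reproduces the matrix, incl. GQ, MQ, phasing and empty panels", {
  for (seed in 1:6) {
    gm <- random_gm(seed)
    f <- tempfile(fileext = ".vcf")
    write_vcf(gm, f)
    expect_true(gm_identical(gm, read_vcf(f)), label = paste("seed", seed))
  }
  # phased calls use the | separator
  gm <- random_gm(2)
  f <- tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  body <- grep("^#", readLines(f), invert = TRUE, value = TRUE)
  expect_true(any(grepl("\\d\\|\\d", body)))
  # header-only VCF for an empty matrix
  empty <- gm_subset(gm, sites = integer(0))
  write_vcf(empty, f)
  expect_equal(sum(!grepl("^#", readLines(f))), 0L)
  expect_equal(n_sites(read_vcf(f)), 0L)
})

test_that("population map enforces its schema and closed superset vocabulary", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tgroup\tsuperset", "s1\tYazd\tnative", "s2\tArian\tcommercial"), f)
  pm <- read_popmap(f)
  expect_s3_class(pm, "pop_map")
  expect_equal(nrow(pm), 2L)
  expect_equal(sort(unique(pm$group)), c("Arian", "Yazd"))
  expect_equal(resolve_samples(pm, "native"), "s1")
  expect_equal(resolve_samples(pm, "Arian"), "s2")

  writeLines(c("sample\tgroup\tsuperset", "s1\tYazd\tbroiler"), f)
  expect_error(read_popmap(f), "superset")
  writeLines(c("sample\tgroup", "s1\tYazd"), f)
  expect_error(read_popmap(f), "superset")     # names missing column
  writeLines(c("sample\tgroup\tsuperset", "s1\tYazd\tnative", "s1\tYazd\tnative"), f)
  expect_error(read_popmap(f), "twice")
  writeLines("sample\tgroup\tsuperset", f)
  expect_error(read_popmap(f), "empty")
})

test_that("quality filter masks low-GQ genotypes and drops low-MQ sites at the stated boundaries", {
  gq <- matrix(c(39, 40, 50, 41, 45, 38), 3, 2)
  mq <- c(25, 24, NA)
  d <- matrix(c(1L, 1L, 1L, 2L, 0L, 1L), 3, 2)
  gm <- gm_from_dosage(d)
  gm$gq <- gq; gm$mq <- mq
  res <- filter_quality(gm)
  expect_equal(unname(res$counts["sites_removed_mq"]), 1L)   # MQ 24 removed
  expect_equal(unname(res$counts["genotypes_masked"]), 2L)   # GQ 39 and 38
  out <- dosage(res$gm)
  expect_equal(n_sites(res$gm), 2L)                # MQ 25 kept (boundary)
  expect_true(is.na(out[1, 1]))                    # GQ 39 -> missing
  expect_false(is.na(out[1, 2]))                   # GQ 41 kept
  # identity when everything passes; filter idempotent
  gm2 <- gm_from_dosage(d); gm2$gq <- gq + 10; gm2$mq <- c(25, 30, 60)
  res2 <- filter_quality(gm2)
  expect_true(gm_identical(res2$gm, gm2))
  twice <- filter_quality(filter_quality(gm)$gm)
  expect_true(gm_identical(twice$gm, res$gm))
  expect_equal(unname(twice$counts["genotypes_masked"]), 0L)
  # sites lacking gq/mq pass unchanged
  gm3 <- gm_from_dosage(d)
  expect_true(gm_identical(filter_quality(gm3)$gm, gm3))
})

test_that("cluster filter removes whole >3-in-10-bp clusters and multiallelic sites", {
  # 4 SNPs inside a 10-bp span: all removed
  gm <- gm_from_dosage(matrix(1L, 5, 2), pos = c(100L, 101L, 103L, 107L, 300L))
  res <- filter_biallelic_and_clusters(gm)
  expect_equal(res$gm$pos, 300L)
  expect_equal(unname(res$counts["sites_removed_cluster"]), 4L)
  # exactly 3 in 10 bp: all kept
  gm2 <- gm_from_dosage(matrix(1L, 3, 2), pos = c(100L, 104L, 109L))
  expect_equal(n_sites(filter_biallelic_and_clusters(gm2)$gm), 3L)
  # triallelic site removed
  gm3 <- gm_from_dosage(matrix(1L, 2, 2), pos = c(100L, 500L))
  gm3$alt[1] <- "C,T"
  res3 <- filter_biallelic_and_clusters(gm3)
  expect_equal(res3$gm$pos, 500L)
  expect_equal(unname(res3$counts["sites_removed_multiallelic"]), 1L)
  # idempotent
  again <- filter_biallelic_and_clusters(res$gm)
  expect_true(gm_identical(again$gm, res$gm))
  # clusters do not leak across chromosomes
  gm4 <- gm_from_dosage(matrix(1L, 4, 2), chrom = c("chr1", "chr1", "chr2", "chr2"),
                        pos = c(100L, 101L, 102L, 103L))
  expect_equal(n_sites(filter_biallelic_and_clusters(gm4)$gm), 4L)
})
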