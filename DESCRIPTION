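Package: popgenscan
Title: Population-Genomic Diversity, Linkage and Selective-Sweep Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genomic analysis of multi-sample diploid
    SNP panels: VCF import with genotype-quality, mapping-quality, biallelic
    and SNP-cluster site filters; per-group diversity summaries (observed and
    expected heterozygosity, proportion of polymorphic sites, method-of-moments
    inbreeding coefficients); windowed nucleotide diversity; linkage
    disequilibrium decay, LD pruning and runs-of-homozygosity detection;
    genomic relationship matrices with principal component analysis; and a
    two-statistic selective-sweep scan combining windowed Weir-Cockerham
    weighted F_ST with the log2 ratio of windowed nucleotide diversity,
    using empirical-quantile outlier calling and gene-interval annotation.
    A Balding-Nichols genotype simulator with controllable divergence, LD,
    inbreeding and planted sweep or autozygosity intervals provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
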