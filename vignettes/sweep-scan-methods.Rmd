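---
title: "Methods: diversity, linkage and selective-sweep scanning in structured populations"
author: "popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, linkage and selective-sweep scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

popgenscan implements the standard desk-scale pipeline for detecting
selection signatures between diverged groups of a species — for example
locally adapted indigenous populations contrasted with intensively
selected commercial lines — from a multi-sample diploid SNP panel. This
vignette is the package's own account of the statistics it computes, the
choices behind them, and what the bundled simulator can and cannot tell
you about real data.

## Input model and site filters

The central container (`geno_matrix`) holds ordered biallelic or
multiallelic SNP sites crossed with samples, storing both allele indices
of each diploid call so phased information survives import. Two
post-calling filters are applied before any statistic:

* **Genotype quality.** Calls with GQ below a threshold (default 40) are
  set to missing; the site itself is retained. Applying GQ per genotype
  rather than per site is the stricter, information-preserving reading of
  the usual "supported by a minimum genotype quality" convention: a site
  with one bad call keeps its good calls.
* **Mapping quality.** Sites with INFO/MQ below a threshold (default 25)
  are removed entirely, since poor mapping indicts the locus, not a
  single sample.
* **Biallelic and cluster filter.** Sites with more than one ALT allele
  are removed, then every SNP lying in any 10-bp interval containing
  more than 3 SNPs is removed — the whole offending cluster, because
  clustered calls are a signature of misalignment rather than of any one
  variant. Any such interval is, without loss of generality, anchored at
  the leftmost SNP it contains, which is how the scan is implemented.

No per-site missingness cutoff is applied after genotype masking; users
can impose one by subsetting. Coordinates are 1-based inclusive
throughout; BED output converts to 0-based half-open at the writer
boundary only. When a VCF lacks `##contig` lengths, the maximum observed
position per chromosome stands in, which truncates trailing windows.

## Diversity statistics

Per group, the package reports observed heterozygosity $H_o$ (fraction of
heterozygous calls, averaged over sites with at least one genotype),
expected heterozygosity $H_e = 2\hat p(1-\hat p)$ (plug-in, no
small-sample correction by default — the convention of the common
genotype-based tools; a correction is available via an argument), and the
proportion of polymorphic SNPs $P_n$.

The per-individual inbreeding coefficient is the method-of-moments excess
homozygosity
$$F = \frac{O_{hom} - E_{hom}}{L - E_{hom}},\qquad
E_{hom} = \sum_j \left(1 - 2\hat p_j(1-\hat p_j)\tfrac{n_j}{n_j-1}\right),$$
with $\hat p_j$ and the allele count $n_j$ taken *within the individual's
group*, over the group's polymorphic sites only. The within-group
reference was chosen because the statistic is reported per individual and
per group; a whole-panel reference would fold population structure into
every individual's $F$. $F$ is invariant to adding sites monomorphic in
the group, and is undefined (reported missing, with a warning) when
$L = E_{hom}$.

Windowed nucleotide diversity uses the unbiased per-site estimator
$\hat\pi_j = c_{ref}c_{alt}/\binom{n}{2}$ — exactly the mean pairwise
difference among the $n$ sampled haplotypes — summed over a window and
divided by the *full window span* in bp. Dividing by the span (rather
than by callable sites) is what windowed-$\pi$ tools report and keeps
ratios between groups interpretable; truncated trailing windows are
flagged so users can drop them. Sliding windows default to 50 kb with a
25 kb step, so each interior site contributes to two windows by design.

## The two-statistic sweep scan

Differentiation uses the Weir–Cockerham moment estimator. For each
biallelic site and two groups with sample sizes $n_i$, alt frequencies
$p_i$ and heterozygote proportions $h_i$, the among-population ($a$),
among-individual ($b$) and within-individual ($c$) components are
computed in closed form (`wc_site_components`), and a window's value is
the **ratio of sums** $\sum a / \sum(a+b+c)$ — the "weighted" estimator,
robust to unequal sample sizes. The mean of per-site ratios is available
as an option (`mean_of_sites = TRUE`) because the two conventions
genuinely differ and published descriptions often blur them; the weighted
form is the default precisely because it is the one described as
"weighted". Negative per-site and per-window values are retained —
clamping at zero would distort the empirical quantiles that define
outliers. Sites monomorphic across both groups contribute nothing and
windows with no usable site are flagged and excluded from ranking. The
tests verify the component equations against an independent nested-ANOVA
evaluation on every two-diploid-per-group genotype configuration.

The second statistic is $\log_2(\pi_A/\pi_B)$ per window. Windows where
either group's diversity is exactly zero are flagged `zero_pi` and
excluded from ranking, with the count reported: a zero can be a real
fixation (the strongest possible sweep signal) or an empty window, and
the ratio cannot distinguish them.

Outliers are the top $k = \lceil q N \rceil$ windows of each statistic
($q$ = 0.05 for $F_{ST}$, 0.01 for the ratio, by default), ties broken by
genomic order so the flagged count is exact by construction. The reported
threshold is the smallest flagged value. The upper tail of the ratio is
the default because, with the native group in the numerator, diversity
loss in the commercial group drives the ratio up; the lower tail is
available for the mirrored contrast. Overlapping or book-ended outlier
windows merge into regions per statistic; the intersection of the two
region sets is the high-confidence candidate list, and genes overlapping
any region by at least 1 bp are reported once with their supporting
statistics.

## Linkage disequilibrium and ROH

Pairwise $r^2$ comes in two modes: haplotype mode
($D^2/p_Aq_Ap_Bq_B$ from phased alleles) and dosage mode (squared Pearson
correlation of 0/1/2 dosages, safe for unphased data). Dosage is the
default for decay and pruning since real panels are phased by external
tools, if at all; the two modes coincide exactly when every diploid is
homozygous. Decay is summarized in right-closed distance bins between the
conventional 1, 3, 5, 15, 60 and 100 kb points, with seeded uniform
subsampling above a per-bin pair budget.

Pruning follows the windowed greedy convention (50 SNPs, step 10,
$r^2 > 0.1$): the worst pair's lower-MAF member is removed (ties: later
position), and passes repeat until a full sweep of the data removes
nothing. Iterating to a fixed point is deliberate — a single pass can
leave a violating pair assembled from the survivors of different windows,
and the package promises the post-condition that a brute-force re-scan
finds none.

ROH detection is the scanning-window heuristic: 50-SNP windows tolerating
at most 1 heterozygous and 5 missing calls, per-SNP hit proportion
threshold 0.05, runs delimited at heterozygous calls, and segments kept
at ≥ 100 kb and ≥ 50 SNPs. Only the length threshold is commonly
adjusted in published analyses; the remaining defaults are the widely
used ones, kept so results are comparable. Segments classify into
0.1–0.4 Mb and > 0.4 Mb, with > 1 Mb — the signature of recent
inbreeding — counted separately as a subset. Because runs end only at
heterozygous calls, a detected segment extends beyond a truly autozygous
interval until the first flanking het; boundary accuracy is therefore
only meaningful relative to the local SNP spacing.

## Relationship matrix and PCA

The GRM is the standardized cross-product
$A_{jk} = M_{jk}^{-1}\sum_i (x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$
over polymorphic biallelic sites, with $M_{jk}$ counted per pair so
missing calls need no imputation. PCA is the eigendecomposition of the
double-centered matrix; coordinates are eigenvector times root
eigenvalue, and each component's largest-magnitude loading is made
positive so runs are bit-for-bit reproducible.

## The simulator: what it emulates, and what it does not

The generator exists so that every downstream statistic can be tested
against known truth. Its components:

* **Divergence.** Ancestral frequencies are uniform on
  (`freq_low`, `freq_high`) (defaults 0.05–0.95, a common-SNP panel);
  each population draws from the Balding–Nichols Beta with variance
  $F\,p(1-p)$. This gives the divergence knob the analytic meaning of an
  expected $F_{ST}$, so parameter recovery is a closed-form check rather
  than a comparison against another simulator. A coalescent model would
  be more realistic but would leave no analytic link to verify against.
* **Linkage.** Haplotypes are mosaics of a finite founder pool
  (`n_founders`, default 40), switching founders between adjacent sites
  with probability $1-e^{-\text{switch\_rate}\,\Delta bp}$. Two knobs
  give monotone, tunable decay — adequate for testing binned $r^2$
  without recombination graphs. `n_founders = Inf` draws sites i.i.d.,
  the no-LD limit; finite pools add of order $1/n_{founders}$ apparent
  differentiation (founder sharing acts like drift), so the analytic
  $F_{ST}$ recovery checks use the infinite-pool limit.
* **Inbreeding.** At each site, an individual's second allele copies its
  first with probability `inbreeding_fis`. The per-site interpretation
  makes every individual's expected $F$ equal to the knob, so mean-$F$
  recovery is limited by SNP count, not by sample count; whole-genome
  copying would make mean $F$ a Bernoulli average over samples and far
  noisier at the same nominal parameter.
* **Sweeps.** Within a target interval, the target group's frequencies
  move toward the nearest boundary, $p' = (1-s)p + s\,[p \ge 0.5]$,
  *before* haplotypes are drawn; $s = 1$ fixes the interval. This keeps
  the induced diversity loss analytic at the cost of not modelling the
  haplotype structure (extended homozygosity around the swept site) that
  real sweeps leave; the package's scan does not use haplotype-based
  statistics, so nothing tested depends on it.
* **Planted ROH.** A sample's second haplotype is overwritten by its
  first over an interval — exact autozygosity with known boundaries.

Default panel size is 2 populations × 20 diploids, one 5-Mb chromosome,
5,000 SNPs (≈ 1 SNP/kb, a down-sampled WGS density); group labels carry
`native`/`commercial` superset tags so pooled contrasts are one flag.
Positions are drawn uniformly without replacement and sorted. All
randomness is a pure function of the config seed, and emitted fixture
directories are byte-identical across reruns.

What the simulator does **not** emulate: demography (growth, migration,
bottlenecks), realistic recombination maps, sequencing error and
genotype-likelihood uncertainty, allele-frequency spectra shaped by
selection at linked sites. Passing tests demonstrate that the estimators
recover what the model plants under clean conditions; they do not
demonstrate robustness to artefacts the model lacks, which is exactly why
the quality and cluster filters in front of the statistics matter on real
data.

## Numerical conventions and problem sizes

* Nearest-rank outlier counts: always exactly $\lceil qN \rceil$ over
  usable windows; ties resolved by genomic order; all-equal inputs flag
  the first $k$ windows with a warning.
* Pruning tie-break: lower MAF removed, then later position — fixed for
  determinism.
* Degenerate inputs: monomorphic pairs are skipped with counts in LD;
  `zero_pi` and `no_usable_sites` windows are excluded from ranking with
  counts; $F$ with a zero denominator is reported missing.
* Every output table carries a `#key=value` echo of the resolved
  configuration, which both documents provenance and exposes
  mixed-configuration output directories.
* The verification suite uses panels of 5,000–40,000 SNPs and 20–100
  diploids: large enough that the stochastic recovery bounds
  (±0.02 on $F_{ST}$, ±0.05 on $F_{is}$, 9/10 planted sweeps) have
  comfortable margins, small enough to run in seconds.

The package exposes its pipeline as plain R functions
(`run_simulate`, `run_scan`, `run_diversity`, `run_ld_decay`,
`run_prune`, `run_roh`, `run_pca`) writing the TSV/BED outputs described
above: in R, composable functions are the natural command surface, and
every "command" is one function call.

## A small worked run

```{r example, eval = FALSE}
sw  <- data.frame(chrom = "chr1", start = 6e6, end = 6.2e6,
                  target_group = "commercial", severity = 1)
cfg <- sim_config(n_diploids_per_pop = 15, n_snps_per_chrom = 8000,
                  chrom_length = 2e7, bn_F = 0.15, n_founders = Inf,
                  sweeps = sw, seed = 19)
dir <- tempfile()
run_simulate(cfg, dir)
res <- run_scan(file.path(dir, "panel.vcf"), file.path(dir, "popmap.tsv"),
                file.path(dir, "scan"))
res$report$regions_intersection   # overlaps the planted 6.0-6.2 Mb sweep
```

## Known limitations

* The scan supports two-group contrasts (optionally pooled via
  supersets); multi-way scans require repeated calls.
* Windowed $F_{ST}$ assumes diploid, biallelic input; multiallelic sites
  are excluded by the filter stage rather than decomposed.
* The ROH heuristic's boundary resolution is one inter-SNP gap at best
  and degrades with sparse panels; its parameters are conventions, not
  estimates.
* LD decay at exact distances (e.g. "$r^2$ at 1 kb") is reported as a
  bin mean over (0,1] kb, not an interpolation; with other bin edges the
  same code reports other conventions.
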