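# invscan

Detection and localization of large (>1 Mb) polymorphic chromosomal
inversions from SNP data, under a memory budget that does not grow with the
number of variants.

## The problem

A polymorphic inversion suppresses recombination between the standard and
inverted orientations, so SNPs inside the inverted segment become strongly
correlated with each other and with each sample's inversion karyotype
(standard homozygote, heterozygote, inverted homozygote). PCA on a genotype
feature matrix therefore recovers inversion structure, and per-SNP
association against the leading principal component localizes it: the
−log₁₀ p-values form a "square wave" over the inverted segment. The
obstacle is scale. A chromosome arm can carry 10⁵–10⁷ SNPs, and the usual
n × 3v one-hot genotype matrix for millions of sites does not fit in the
memory of an ordinary workstation.

`invscan` avoids ever building that matrix. Variants are streamed from VCF
in fixed-size batches, and each site's alleles are folded directly into an
n × k matrix by feature hashing: the allele named
`chromosome_position_allele` is assigned column
`abs(murmur3(name)) mod k`, and a sample's copy count of that allele
(0, 1 or 2) is added there. Memory is O(n·k) plus one batch, independent of
the number of variants v. PCA is then run on the reduced matrix as a second
stage of dimensionality reduction.

Downstream, the package implements:

- **PC–SNP association scan** — per SNP, a one-way ANOVA F-test of the
  selected PC coordinate across the three genotype classes (unknown
  genotypes excluded), streamed with bounded memory; results are written as
  a Manhattan table/plot.
- **Boundary calling** — SNPs are flagged at the Bonferroni threshold
  `0.01 / num_snps`; the chromosome is tiled with 10 kb windows; each
  window's significant-SNP fraction is tested against the chromosome-wide
  fraction p₀ with a one-sided exact binomial tail; windows pass at
  `0.0001 / num_windows`; the call spans the centers of the left-most and
  right-most significant windows.
- **Evaluation** — Sørensen–Dice overlap
  `DSC = 2|P∩T| / (|P|+|T|)` between predicted and known intervals, with
  endpoints rounded to 0.1 Mb.
- **Dimension heuristic** — the Johnson–Lindenstrauss bound
  `k ≥ 4·ln(n) / (ε²/2 − ε³/3)` with ε chosen below `l/m` (inversion extent
  over background extent) suggests how many hashed columns suffice to keep
  karyotype clusters separated.
- **Simulator** — synthetic VCFs with a planted inversion (Hardy–Weinberg
  karyotypes, perfectly linked SNPs inside the interval, variable
  background SNPs outside) for testing and calibration without any data
  download.

## Worked example

Simulate a 10 Mb chromosome for 100 samples with an inversion planted at
2.0–4.0 Mb (inverted-orientation frequency 0.3, 2,000 linked SNPs, 8,000
background SNPs), pick the hashed dimensionality with the JL heuristic,
and run the full scan:

```r
library(invscan)

vcf <- tempfile(fileext = ".vcf")
sim <- simulate_inversion_vcf(vcf, n_samples = 100, chrom = "2L",
                              chrom_length_bp = 1e7,
                              inversion_start_bp = 2e6,
                              inversion_end_bp = 4e6,
                              inversion_freq = 0.3,
                              l = 2000, m = 8000, seed = 7)

suggest_dimensions(n = 100, l = 2000, m = 8000)
#> $epsilon
#> [1] 0.2475
#> $k
#> [1] 720

res <- run_inversion_scan(vcf, k = 720, chrom_extent = 1e7)
res$scores
#> <pc_scores> 100 samples x 10 components; explained variance ratio:
#>   0.223 0.015 0.015 0.015 0.014 0.014 0.014 0.013 0.013 0.013
res$call
#> <inversion_call> 2L:2.015-3.975 Mb (82 significant windows)

genotype_separability(res$scores, sim$truth$genotypes, seed = 1)$accuracy
#> [1] 1

dice_percent(dice_overlap(res$call, genomic_interval("2L", 2, 4)))
#> [1] 100
```

PC1 alone explains ~22% of the variance (the inversion), karyotypes are
perfectly separable in the PC1/PC2 plane, and the boundary call lands
within two windows of the planted breakpoints — a 100.0% Dice overlap at
0.1 Mb resolution.

The same workflow is available from the shell via the bundled CLI
(`inst/cli/invscan`), decomposed into `simulate`, `import`, `pca`,
`separability`, `associate`, `boundaries`, `dice` and `jl-dims`
subcommands; every run writes a JSON manifest recording parameters, seeds
and input checksums.

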