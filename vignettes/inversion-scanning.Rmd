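---
title: "Memory-bounded inversion scanning: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-bounded inversion scanning: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscan)
```

## The model

A large polymorphic inversion suppresses recombination between
orientations, so mutations accumulate privately within each orientation.
SNPs inside the inverted segment are then in strong mutual linkage and
track each sample's inversion karyotype — standard homozygote,
heterozygote, or inverted homozygote. Two consequences drive this package:

1. PCA of a genotype feature matrix places samples along karyotype axes:
   the leading component orders the three karyotype clusters.
2. A per-SNP test of association between genotype class and the leading
   PC coordinate is strong for SNPs inside the inversion and null outside,
   producing a square-wave Manhattan profile whose edges are the
   breakpoints.

Both steps tolerate aggressive, structure-agnostic dimensionality
reduction of the SNP axis, which is what makes the streaming construction
possible.

### Feature encodings

Two encoders over the same biallelic-SNP stream:

* **Categorical** (`build_categorical_matrix`): one 3-column one-hot group
  per site in the order (HOM_REF, HOM_ALT, HET); unknown genotypes leave
  the whole group at zero. Exact, `O(nv)` storage. In this geometry the
  three karyotype clusters of an inversion sit on an equilateral triangle
  (every pair of distinct genotypes differs in exactly two of three
  columns per site), so no single PC need order them linearly.
* **Hashed** (`build_hashed_matrix`): each site allele is named
  `chrom_pos_allele`; its column is `abs(murmur3(name)) mod k`; a sample's
  copy count of the allele (2 for the matching homozygote, 1 each for a
  heterozygote, 0 otherwise) is accumulated there; unknown genotypes add
  nothing. `O(nk)` storage, independent of v. Both alleles of a site are
  hashed — a standard homozygote contributes two copies of the reference
  allele's key — so every called genotype adds exactly two allele copies
  and row sums equal twice the per-sample call count, an invariant the
  tests rely on. This encoding is linear in allele dosage, so karyotype
  clusters are collinear along the dosage axis.

Hash collisions merely add columns of the exact allele-copy matrix
together, i.e. the hashed matrix is a fixed random bucket projection of
the exact matrix (`bucket_projection_oracle` verifies this
entry-for-entry). Signs are not alternated across buckets: allele counts
are non-negative, and keeping them so preserves the row-sum invariant.

### Choosing k

Feature hashing behaves like a crude random projection, so the
Johnson–Lindenstrauss bound

$$k \ge \frac{4\ln(n)}{\varepsilon^2/2 - \varepsilon^3/3}$$

links the number of retained columns to the worst-case relative distortion
ε of pairwise sample distances. For an inversion spanning `l` linked SNPs
among `m` background SNPs, the squared-distance gap between samples of
different karyotypes is at least a fraction `l/m` of the background
distance, so any ε strictly below `l/m` preserves the cluster gap.
`suggest_epsilon` backs off 1% below `min(l/m, 0.999)`; `min_dimensions`
evaluates the bound with the natural logarithm and truncates toward zero.
Truncation (rather than the ceiling a strict lower-bound reading implies)
is deliberate: the heuristic is a guidance value, not a guarantee, the two
differ by at most one column, and the truncated convention is the one this
package standardizes and tests. `l` and `m` can be given as SNP counts or
as genomic spans — only their ratio enters.

### Association scan

For each SNP the selected PC coordinates are grouped by genotype class,
samples with unknown genotype are dropped, and a one-way ANOVA F-test
p-value is computed from the closed-form between/within decomposition
(vectorized over a batch; `aov` is the per-SNP oracle in the test suite).
Degenerate SNPs — monomorphic among called samples, or without residual
degrees of freedom — receive p = 1 rather than being dropped, so the SNP
count used for Bonferroni correction downstream equals the number of
scanned SNPs. p-values are clamped at 1e-300 before the −log₁₀ transform
so Manhattan tables stay finite.

### Boundary calling

SNPs are flagged when `p < snp_alpha / num_snps` (strict inequality;
defaults `snp_alpha = 0.01`). The chromosome is tiled from coordinate 0
with non-overlapping windows of `window_size` bp (default 10 kb). With
`p0` the chromosome-wide flagged fraction, each window with `s` of `n`
SNPs flagged is scored by the exact binomial tail `P[X ≥ s]`,
`X ~ Binomial(n, p0)`; windows with no SNPs or no flagged SNPs score 1.
Windows pass at `p < window_alpha / num_windows` (default
`window_alpha = 1e-4`), where `num_windows` counts **all** tiled windows:
empty windows are assigned p-values and therefore belong to the tested
family. The inversion call spans the centers of the extreme significant
windows; no significant window means no call. Zero-anchored tiling, the
strict inequalities, and the all-windows family are deliberate
conventions chosen for reproducibility where several readings are
defensible; each is pinned by a test.

### Interval evaluation

`dice_overlap` rounds endpoints to the nearest 0.1 Mb (half away from
zero), then computes `2|P∩T| / (|P|+|T|)` with continuous lengths.
Percentages are reported at one decimal, round-half-up. Rounding half up
rather than truncating, and measuring continuous lengths rather than
counting inclusive 0.1 Mb units, are the package's fixed conventions; no
single convention reproduces every historically published rounded
percentage of this statistic, and when comparing against external tables
a one-last-digit discrepancy should be attributed to the source's own
rounding rather than to the measure.

## The simulator

`simulate_inversion_vcf` emulates exactly the structure the detector
exploits, and deliberately nothing else:

* karyotypes drawn from Hardy–Weinberg proportions at `inversion_freq`
  (default 0.3 — a moderately common inversion);
* `l` linked SNPs (default 2,000) at uniform positions inside the planted
  interval (default 2.0–4.0 Mb of a 10 Mb chromosome), each mirroring the
  sample's karyotype exactly, with per-site randomized ref/alt polarity
  and optional per-call `leakage` to an independent Hardy–Weinberg draw;
* `m` background SNPs (default 8,000) strictly outside the interval with
  allele frequencies uniform on (0.05, 0.95), resampled until variable;
* optional uniform genotype masking at `missing_rate` (default 0).

Defaults were fixed once, before any benchmarking, as a desk-scale
portrait of the real use case (one inversion per arm, ≥10% frequency,
SNP density of order 1/kb). Not emulated: linkage-disequilibrium decay,
recombination or gene flux within the inversion, population structure,
multiple or overlapping inversions, genotyping error beyond missingness.
Passing end-to-end tests on these simulations therefore demonstrates that
the machinery is correct and the statistical conventions behave as
designed — not that real inversions at difficult frequencies or with
eroded linkage will be recovered at the same rates.

## Numerical and design choices

* **Hash**: MurmurHash3 x86_32 of the key bytes, seeded (default 0),
  interpreted as a signed 32-bit value; `abs` is taken in 64-bit
  arithmetic so the INT32_MIN case is defined. A pure-R reimplementation
  in the test helpers and frozen reference values pin the compiled kernel.
* **Streaming**: `readLines` on a (gz)file connection in `batch_size`
  batches (default 10,000 — small enough to bound memory, large enough to
  amortize parsing); batch-size invariance of every downstream product is
  tested. Phased and unphased calls are equivalent; any call containing
  `.` (including half-calls) is unknown; multi-allelic and non-SNP records
  are skipped and counted.
* **PCA**: exact SVD via `prcomp`, centered, unscaled; scores whitened to
  unit variance per component (zero-variance components left at zero).
  Deterministic at the package's intended scale (n up to a few hundred,
  k up to ~10⁴), which is why no randomized solver is used.
* **Separability check**: stratified 75/25 split (seeded), multinomial
  logistic regression on PC1/PC2 only, held-out accuracy. A fully
  converged maximum-likelihood fit (`nnet::multinom`, no regularization
  beyond the default) replaces stochastic-gradient training: on a
  2-dimensional input the converged optimum is what an SGD fit
  approximates, without a learning-rate schedule to tune.
* **Windows**: the default chromosome extent is the largest SNP position
  rounded up to the next window multiple (strictly covering, so a
  position exactly on a window boundary still falls inside the tiling);
  supply the true chromosome length when it is known.

## Known limitations

* Localization resolution is limited by window granularity interacting
  with the exact binomial threshold. With the default 10 kb windows, a
  chromosome-wide flagged fraction of `p0` and an expected `λ` flagged
  SNPs per fully-linked window, a window is callable only when it holds at
  least `s* = ⌈ln(window_alpha / num_windows) / ln(p0)⌉` SNPs. When λ is
  near `s*` (e.g. λ = 10 against `s* = 11` at `p0 = 0.2` with 1,000
  windows), boundary windows are flagged only stochastically and the
  called edge wanders inward by a few windows. Enlarging windows, or
  lowering SNP density per window, shifts this trade-off; the package
  reports `p0` and `num_windows` so the margin can be checked.
* One call per chromosome: the leftmost/rightmost rule assumes a single
  contiguous inversion; overlapping inversion systems are out of scope.
* The separability evaluation is a diagnostic of cluster structure, not a
  karyotype caller for unlabeled samples.
* The categorical encoder is exact but `O(nv)`; it exists as the reference
  path and for modest inputs, not for million-SNP arms.
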