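Package: invscan
Title: Memory-Bounded Detection and Localization of Large Polymorphic
    Inversions from SNP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and localizes large (>1 Mb) polymorphic chromosomal
    inversions from SNP genotypes in VCF files under a fixed memory budget.
    Variants are streamed in batches and accumulated directly into a
    feature-hashed allele-count matrix (or a full categorical genotype
    matrix), so the number of variants never enters the memory footprint.
    Principal component analysis on the reduced matrix recovers inversion
    karyotype structure; per-SNP one-way ANOVA tests of genotype against a
    principal component produce a Manhattan table; a windowed binomial
    enrichment scan with Bonferroni control calls inversion boundaries; and
    Sorensen-Dice interval overlap scores predictions against known
    inversions.  A Johnson-Lindenstrauss heuristic suggests the hashed
    dimensionality, and a bundled simulator generates VCFs with a planted
    inversion for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    nnet,
    optparse,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
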