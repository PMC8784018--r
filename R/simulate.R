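## Synthetic VCFs with a planted polymorphic inversion.
##
## Each sample draws an inversion genotype from Hardy-Weinberg proportions
## at the inverted-orientation frequency.  l "linked" SNPs inside the
## inversion interval mirror the sample's inversion genotype exactly
## (recombination suppression at its idealized limit); m background SNPs
## outside the interval draw an alternate-allele frequency from
## Uniform(0.05, 0.95) and genotypes from Hardy-Weinberg, resampled until
## the site is variable.  Ref/alt polarity of linked sites is randomized so
## detection cannot exploit a fixed orientation of the encoding.

#' Simulate a VCF with one planted polymorphic inversion
#'
#' @param out_vcf output VCF path (plain text, VCF 4.2)
#' @param n_samples number of diploid samples
#' @param chrom chromosome name used in the VCF
#' @param chrom_length_bp chromosome length in bp
#' @param inversion_start_bp,inversion_end_bp planted inversion interval
#' @param inversion_freq allele frequency of the inverted orientation
#' @param l number of inversion-linked SNPs (uniform positions inside the
#'   interval)
#' @param m number of background SNPs (uniform positions outside the
#'   interval)
#' @param missing_rate per-genotype probability of masking to `./.`
#' @param leakage per-genotype probability that a linked SNP call is
#'   replaced by an independent Hardy-Weinberg draw (imperfect linkage)
#' @param seed RNG seed; the output is fully reproducible from it
#' @param truth_json optional path for a JSON truth sidecar (interval,
#'   per-sample inversion genotypes)
#' @return invisibly, a list with `vcf`, `truth` (list: `chrom`,
#'   `interval_bp`, `genotypes` coded 0/1/2 copies of the inverted
#'   orientation, `sample_ids`)
#' @export
simulate_inversion_vcf <- function(out_vcf,
                                   n_samples = 100L,
                                   chrom = "2L",
                                   chrom_length_bp = 1e7,
                                   inversion_start_bp = 2e6,
                                   inversion_end_bp = 4e6,
                                   inversion_freq = 0.3,
                                   l = 2000L,
                                   m = 8000L,
                                   missing_rate = 0,
                                   leakage = 0,
                                   seed = 1L,
                                   truth_json = NULL) {
  if (l + m == 0L) stop("input error: l + m must be positive")
  if (inversion_start_bp < 1 || inversion_end_bp > chrom_length_bp ||
      inversion_start_bp >= inversion_end_bp)
    stop("input error: inversion interval must lie within the chromosome")
  if (inversion_freq <= 0 || inversion_freq >= 1)
    stop("parameter error: inversion_freq must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1 || leakage < 0 || leakage >= 1)
    stop("parameter error: missing_rate and leakage must be in [0, 1)")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  n <- as.integer(n_samples)
  q <- inversion_freq
  # per-sample inversion genotypes: copies of the inverted orientation;
  # re-drawn (bounded tries) if monomorphic, which would leave no signal
  for (try in 1:100) {
    inv_geno <- stats::rbinom(n, 2L, q)
    if (l == 0L || length(unique(inv_geno)) >= 2L) break
  }

  pos_linked <- if (l > 0L)
    sample_unique_positions(l, inversion_start_bp, inversion_end_bp)
  else integer()
  pos_bg <- if (m > 0L)
    sample_background_positions(m, chrom_length_bp, inversion_start_bp,
                                inversion_end_bp)
  else integer()

  v <- l + m
  pos <- c(pos_linked, pos_bg)
  linked <- c(rep(TRUE, l), rep(FALSE, m))
  ord <- order(pos)
  pos <- pos[ord]; linked <- linked[ord]

  geno <- matrix(0L, nrow = v, ncol = n)
  if (l > 0L) {
    lg <- matrix(rep(inv_geno, times = l), nrow = l, byrow = TRUE)
    if (leakage > 0) {
      leak <- matrix(stats::runif(l * n) < leakage, nrow = l)
      lg[leak] <- stats::rbinom(sum(leak), 2L, q)
    }
    flip <- stats::runif(l) < 0.5   # per-site ref/alt polarity
    lg[flip, ] <- 2L - lg[flip, ]
    geno[linked, ] <- lg
  }
  if (m > 0L) {
    bg <- matrix(0L, nrow = m, ncol = n)
    for (j in seq_len(m)) {
      repeat {
        maf <- stats::runif(1, 0.05, 0.95)
        gj <- stats::rbinom(n, 2L, maf)
        if (length(unique(gj)) >= 2L) break   # site must be variable
      }
      bg[j, ] <- gj
    }
    geno[!linked, ] <- bg
  }

  gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = v)
  if (missing_rate > 0)
    gt[matrix(stats::runif(v * n) < missing_rate, nrow = v)] <- "./."

  base_pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C"),
                       ncol = 2L, byrow = TRUE)
  pick <- sample.int(4L, v, replace = TRUE)
  ref <- base_pairs[pick, 1L]
  alt <- base_pairs[pick, 2L]

  sample_ids <- sprintf("S%03d", seq_len(n))
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", chrom,
                      as.integer(chrom_length_bp)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  fixed <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                 sep = "\t")
  body <- do.call(paste, c(list(fixed), as.data.frame(gt), list(sep = "\t")))
  writeLines(c(header, body), out_vcf)

  truth <- list(chrom = chrom,
                interval_bp = c(inversion_start_bp, inversion_end_bp),
                inversion_freq = inversion_freq,
                genotypes = inv_geno, sample_ids = sample_ids,
                l = l, m = m, seed = seed)
  if (!is.null(truth_json))
    jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = out_vcf, truth = truth))
}

sample_unique_positions <- function(count, lo, hi) {
  span <- hi - lo + 1
  if (count > span) stop("input error: more SNPs than positions in interval")
  sort(sample.int(span, count) + lo - 1)
}

sample_background_positions <- function(count, chrom_len, inv_lo, inv_hi) {
  left <- max(0, inv_lo - 1)               # [1, inv_lo)
  right <- max(0, chrom_len - inv_hi)      # (inv_hi, chrom_len]
  if (left + right < count)
    stop("input error: not enough positions outside the inversion")
  n_left <- stats::rbinom(1L, count, left / (left + right))
  p_left <- if (n_left > 0) sample.int(left, n_left) else integer()
  p_right <- if (count - n_left > 0)
    sample.int(right, count - n_left) + inv_hi else integer()
  sort(c(p_left, p_right))
}
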