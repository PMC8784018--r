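## Feature matrix construction.
##
## Two encoders over the same variant stream:
##  * categorical -- n x 3v one-hot genotype matrix (the exact, memory-hungry
##    representation; one 3-column group per site in order HOM_REF, HOM_ALT,
##    HET);
##  * hashed -- n x k allele-copy-count matrix built with the hashing trick:
##    each site allele is named "chrom_pos_allele", its column is
##    abs(murmur3(name)) %% k, and a sample's copy count of that allele
##    (0/1/2) is accumulated into the column.  k is fixed by the user, so
##    memory is O(n*k) regardless of the number of variants.

#' Allele keys for the hashing trick
#'
#' @param chrom,pos,allele vectors of equal length (recycled as in `paste`)
#' @return character vector of `"chromosome_position_allele"` keys
#' @export
allele_key <- function(chrom, pos, allele) {
  paste(chrom, pos, allele, sep = "_")
}

#' Map allele keys to hashed column indices
#'
#' Computes `abs(hash(key)) %% k` with a seedable, platform-stable signed
#' 32-bit MurmurHash3.  The absolute value is taken in 64-bit arithmetic so
#' the minimum-integer case is well defined.  No sign alternation is applied
#' to the accumulated values.
#'
#' @param keys character vector of allele keys (see [allele_key()])
#' @param k number of hashed columns (>= 1)
#' @param hash_seed integer hash seed (default 0)
#' @return integer vector of 0-based column indices in `[0, k)`
#' @export
#' @examples
#' hash_column("2L_34534_T", k = 1000)
hash_column <- function(keys, k, hash_seed = 0L) {
  k <- as.numeric(k)
  if (length(k) != 1L || is.na(k) || k < 1)
    stop("parameter error: k must be a positive integer")
  as.integer(murmur32_abs(as.character(keys), as.integer(hash_seed)) %% k)
}

new_feature_matrix <- function(values, sample_ids, encoder, k,
                               hash_seed = NA_integer_, n_variants,
                               n_skipped = 0L) {
  dimnames(values) <- list(sample_ids, NULL)
  structure(list(values = values, sample_ids = sample_ids, encoder = encoder,
                 k = as.integer(k), hash_seed = hash_seed,
                 n_variants = as.integer(n_variants),
                 n_skipped = as.integer(n_skipped)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", x$encoder, ":", nrow(x$values), "samples x",
      x$k, "columns (", x$n_variants, "variants consumed,",
      x$n_skipped, "records skipped )\n")
  invisible(x)
}

#' Build the feature-hashed allele-count matrix from a VCF stream
#'
#' Initializes a dense `n x k` matrix of zeros and folds each batch of
#' variants into it: per called genotype, 2 copies of the homozygous allele
#' or 1 copy each of the reference and alternate allele are added to the
#' hashed columns of the corresponding allele keys.  Unknown genotypes
#' contribute nothing.  Per-batch intermediates are discarded, so memory is
#' `O(n*k)` plus one batch, independent of the number of variants.
#'
#' @param vcf path to a VCF file
#' @param k number of hashed columns (see [min_dimensions()] for guidance)
#' @param hash_seed integer seed of the column hash (default 0)
#' @param batch_size variants per streamed batch
#' @param chroms optional chromosome filter
#' @return a `feature_matrix` with `encoder = "hashed"`
#' @export
build_hashed_matrix <- function(vcf, k, hash_seed = 0L, batch_size = 10000L,
                                chroms = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("parameter error: k must be >= 1")
  samples <- vcf_samples(vcf)
  n <- length(samples)
  X <- matrix(0, nrow = n, ncol = k)
  n_variants <- 0L
  add_batch <- function(b) {
    n_variants <<- n_variants + length(b$pos)
    X <<- X + hashed_batch_increment(b, n, k, hash_seed)
  }
  stats <- stream_variants(vcf, add_batch, batch_size = batch_size,
                           chroms = chroms)
  if (n_variants == 0L)
    stop("input error: VCF stream yielded zero biallelic SNPs")
  new_feature_matrix(X, samples, "hashed", k, as.integer(hash_seed),
                     n_variants, stats$n_skipped)
}

# n x k increment contributed by one variant batch: sparse incidence of
# hashed columns, weighted by per-sample allele copy counts.
hashed_batch_increment <- function(b, n, k, hash_seed) {
  v <- length(b$pos)
  col_ref <- hash_column(allele_key(b$chrom, b$pos, b$ref), k, hash_seed) + 1L
  col_alt <- hash_column(allele_key(b$chrom, b$pos, b$alt), k, hash_seed) + 1L
  g <- b$geno                      # v x n, codes 0/1/2/NA
  alt_copies <- g
  alt_copies[is.na(alt_copies)] <- 0L
  ref_copies <- 2L - g
  ref_copies[is.na(ref_copies)] <- 0L
  inc_ref <- Matrix::sparseMatrix(i = seq_len(v), j = col_ref, x = 1,
                                  dims = c(v, k))
  inc_alt <- Matrix::sparseMatrix(i = seq_len(v), j = col_alt, x = 1,
                                  dims = c(v, k))
  as.matrix(t(ref_copies) %*% inc_ref + t(alt_copies) %*% inc_alt)
}

#' Build the categorical (one-hot genotype) feature matrix from a VCF stream
#'
#' Site `j` (0-based, in stream order) occupies columns `3j+1 .. 3j+3` in
#' the order homozygous reference, homozygous alternate, heterozygous;
#' exactly one of the three is 1 for a called genotype and all three are 0
#' for an unknown genotype.  Storage is `O(n*v)`.
#'
#' @inheritParams build_hashed_matrix
#' @return a `feature_matrix` with `encoder = "categorical"` and `k = 3v`
#' @export
build_categorical_matrix <- function(vcf, batch_size = 10000L, chroms = NULL) {
  samples <- vcf_samples(vcf)
  n <- length(samples)
  blocks <- list()
  add_batch <- function(b) {
    v <- length(b$pos)
    block <- matrix(0, nrow = n, ncol = 3L * v)
    g <- t(b$geno)                 # n x v
    called <- which(!is.na(g), arr.ind = TRUE)
    if (nrow(called) > 0L) {
      code <- g[called]
      # genotype code -> offset within the 3-column group:
      # HOM_REF (0) -> 1, HOM_ALT (2) -> 2, HET (1) -> 3
      offset <- ifelse(code == 0L, 1L, ifelse(code == 2L, 2L, 3L))
      block[cbind(called[, 1L], 3L * (called[, 2L] - 1L) + offset)] <- 1
    }
    blocks[[length(blocks) + 1L]] <<- block
  }
  stats <- stream_variants(vcf, add_batch, batch_size = batch_size,
                           chroms = chroms)
  if (length(blocks) == 0L)
    stop("input error: VCF stream yielded zero biallelic SNPs")
  X <- do.call(cbind, blocks)
  new_feature_matrix(X, samples, "categorical", ncol(X), NA_integer_,
                     ncol(X) / 3L, stats$n_skipped)
}

#' Exact bucket-projection oracle for the hashed matrix
#'
#' Test oracle: materializes the exact `n x 2v` allele-copy-count matrix
#' (one column per site allele, in stream order ref then alt), then sums
#' columns whose allele keys hash to the same bucket.  Must equal
#' [build_hashed_matrix()] entry-for-entry; intended for small inputs only.
#'
#' @inheritParams build_hashed_matrix
#' @return a `feature_matrix` with `encoder = "hashed"`
#' @export
bucket_projection_oracle <- function(vcf, k, hash_seed = 0L, chroms = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("parameter error: k must be >= 1")
  samples <- vcf_samples(vcf)
  n <- length(samples)
  cols <- list()     # exact allele-copy columns
  buckets <- integer()
  add_batch <- function(b) {
    g <- t(b$geno)                                 # n x v
    alt_copies <- g; alt_copies[is.na(alt_copies)] <- 0L
    ref_copies <- 2L - g; ref_copies[is.na(ref_copies)] <- 0L
    interleaved <- matrix(0, nrow = n, ncol = 2L * ncol(g))
    interleaved[, seq(1L, 2L * ncol(g), by = 2L)] <- ref_copies
    interleaved[, seq(2L, 2L * ncol(g), by = 2L)] <- alt_copies
    cols[[length(cols) + 1L]] <<- interleaved
    kr <- hash_column(allele_key(b$chrom, b$pos, b$ref), k, hash_seed)
    ka <- hash_column(allele_key(b$chrom, b$pos, b$alt), k, hash_seed)
    buckets <<- c(buckets, as.vector(rbind(kr, ka)))
  }
  stats <- stream_variants(vcf, add_batch, chroms = chroms)
  if (length(cols) == 0L)
    stop("input error: VCF stream yielded zero biallelic SNPs")
  A <- do.call(cbind, cols)                        # n x 2v exact matrix
  X <- matrix(0, nrow = n, ncol = k)
  for (b in unique(buckets))
    X[, b + 1L] <- rowSums(A[, buckets == b, drop = FALSE])
  new_feature_matrix(X, samples, "hashed", k, as.integer(hash_seed),
                     ncol(A) / 2L, stats$n_skipped)
}

#' Persist a feature matrix as TSV plus a JSON sidecar
#'
#' @param fm a `feature_matrix`
#' @param prefix output path prefix; writes `<prefix>.tsv` (values, one row
#'   per sample) and `<prefix>.json` (sample ids, encoder, k, hash seed)
#' @return the prefix, invisibly
#' @export
write_feature_matrix <- function(fm, prefix) {
  stopifnot(inherits(fm, "feature_matrix"))
  utils::write.table(fm$values, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(sample_ids = fm$sample_ids, encoder = fm$encoder, k = fm$k,
               hash_seed = fm$hash_seed, n_variants = fm$n_variants,
               n_skipped = fm$n_skipped)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param prefix path prefix used when writing
#' @return a `feature_matrix`
#' @export
read_feature_matrix <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  values <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t",
                                        header = FALSE))
  new_feature_matrix(values, meta$sample_ids, meta$encoder, meta$k,
                     if (is.null(meta$hash_seed)) NA_integer_ else meta$hash_seed,
                     meta$n_variants, meta$n_skipped)
}
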