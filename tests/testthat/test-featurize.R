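test_that("hash_column matches an independent MurmurHash3 implementation", {
  expect_equal(invscan:::murmur32("2L_34534_T", 0L), 1753377536L)
  expect_equal(invscan:::murmur32("2R_9897_A", 0L), -928887175L)
  expect_equal(hash_column("2L_34534_T", 1000), 536L)

  set.seed(5)
  keys <- replicate(40, paste0(sample(c(LETTERS, 0:9, "_"), sample(1:20, 1),
                                      replace = TRUE), collapse = ""))
  for (seed in c(0L, 42L)) {
    ours <- invscan:::murmur32(keys, seed)
    ref <- vapply(keys, r_murmur32, 0, seed = seed)
    expect_equal(as.numeric(ours), unname(ref))
    expect_equal(hash_column(keys, 97, seed),
                 vapply(keys, r_hash_column, 0, k = 97, seed = seed),
                 ignore_attr = TRUE)
  }
})

test_that("hash_column is deterministic and respects k", {
  expect_identical(hash_column("anything", 1), 0L)
  expect_identical(hash_column("abc", 64, 9), hash_column("abc", 64, 9))
  expect_error(hash_column("abc", 0), "k must be")
  idx <- hash_column(paste0("key", 1:500), 16)
  expect_true(all(idx >= 0 & idx < 16))
})

test_that("categorical encoding follows the one-hot site-group layout", {
  # 1 sample: HOM_ALT -> [0,1,0]; UNKNOWN -> [0,0,0]
  vcf <- make_vcf(tempfile(fileext = ".vcf"), "1", c(100, 200), c("A", "C"),
                  c("G", "T"), matrix(c("1/1", "./."), 2, 1))
  fm <- build_categorical_matrix(vcf)
  expect_equal(unname(fm$values), matrix(c(0, 1, 0, 0, 0, 0), 1))
  expect_equal(fm$k, 6L)
  expect_equal(fm$n_variants, 2L)

  # 2 samples x 3 SNPs all HET -> row [0,0,1, 0,0,1, 0,0,1]
  vcf2 <- make_vcf(tempfile(fileext = ".vcf"), "1", c(1, 2, 3) * 100,
                   rep("A", 3), rep("G", 3), matrix("0/1", 3, 2))
  fm2 <- build_categorical_matrix(vcf2)
  expect_equal(unname(fm2$values),
               matrix(rep(c(0, 0, 1), 3), 2, 9, byrow = TRUE))
  expect_equal(rowSums(fm2$values), c(S1 = 3, S2 = 3))
})

test_that("categorical row sums count called genotypes, one per site group", {
  set.seed(12)
  fix <- make_random_vcf(tempfile(fileext = ".vcf"), n = 9, v = 40,
                         missing_rate = 0.2)
  fm <- build_categorical_matrix(fix$path)
  called_per_sample <- colSums(!is.na(fix$geno))
  expect_equal(unname(rowSums(fm$values)), unname(called_per_sample))
  for (j in seq_len(40)) {
    group <- fm$values[, (3 * j - 2):(3 * j)]
    expect_true(all(rowSums(group) %in% c(0, 1)))
  }
})

test_that("hashed increments follow the allele-copy rule", {
  # HET with non-colliding keys: two entries of 1, row sum 2
  vcf <- make_vcf(tempfile(fileext = ".vcf"), "1", 100, "A", "G",
                  matrix("0/1", 1, 1))
  fm <- build_hashed_matrix(vcf, k = 4096)
  expect_equal(sum(fm$values == 1), 2)
  expect_equal(sum(fm$values), 2)

  # HOM_REF: a single entry of 2 (the reference allele's bucket)
  vcf2 <- make_vcf(tempfile(fileext = ".vcf"), "1", 100, "A", "G",
                   matrix("0/0", 1, 1))
  fm2 <- build_hashed_matrix(vcf2, k = 4096)
  expect_equal(sum(fm2$values == 2), 1)
  expect_equal(sum(fm2$values), 2)
  expect_equal(which(fm2$values == 2) - 1L, hash_column("1_100_A", 4096))

  # UNKNOWN adds nothing
  vcf3 <- make_vcf(tempfile(fileext = ".vcf"), "1", 100, "A", "G",
                   matrix("./.", 1, 1))
  fm3 <- build_hashed_matrix(vcf3, k = 4096)
  expect_equal(sum(fm3$values), 0)
})

test_that("k = 1 collapses to twice the called-genotype count", {
  set.seed(3)
  fix <- make_random_vcf(tempfile(fileext = ".vcf"), n = 6, v = 30,
                         missing_rate = 0.15)
  fm <- build_hashed_matrix(fix$path, k = 1)
  expect_equal(as.vector(fm$values), 2 * unname(colSums(!is.na(fix$geno))))
})

test_that("hashed row sums and total mass conserve allele copies", {
  set.seed(21)
  fix <- make_random_vcf(tempfile(fileext = ".vcf"), n = 8, v = 60,
                         missing_rate = 0.1)
  fm <- build_hashed_matrix(fix$path, k = 32)
  called <- colSums(!is.na(fix$geno))
  expect_equal(unname(rowSums(fm$values)), 2 * unname(called))
  expect_equal(sum(fm$values), 2 * sum(called))
  expect_true(all(fm$values >= 0))
  expect_true(all(fm$values <= 2 * 60))
})

test_that("hashed matrix is invariant to batch size", {
  set.seed(8)
  fix <- make_random_vcf(tempfile(fileext = ".vcf"), n = 5, v = 37)
  ref <- build_hashed_matrix(fix$path, k = 16, batch_size = 10000)
  for (bs in c(1, 3, 37)) {
    expect_equal(build_hashed_matrix(fix$path, k = 16, batch_size = bs)$values,
                 ref$values)
  }
})

test_that("hashed matrix equals the exact bucket-projection oracle", {
  set.seed(99)
  for (rep in 1:5) {
    fix <- make_random_vcf(tempfile(fileext = ".vcf"),
                           n = sample(2:12, 1), v = sample(20:80, 1),
                           missing_rate = 0.1)
    k <- sample(c(2, 7, 16, 64), 1)
    fm <- build_hashed_matrix(fix$path, k = k, batch_size = 17)
    oracle <- bucket_projection_oracle(fix$path, k = k)
    expect_identical(fm$values, oracle$values)
  }
})

test_that("forced collisions (k = 2) sum the collided allele columns", {
  vcf <- make_vcf(tempfile(fileext = ".vcf"), "1", c(100, 200), c("A", "C"),
                  c("G", "T"), matrix(c("0/0", "1/1"), 2, 1))
  fm <- build_hashed_matrix(vcf, k = 2)
  oracle <- bucket_projection_oracle(vcf, k = 2)
  expect_identical(fm$values, oracle$values)
  expect_equal(sum(fm$values), 4)
})

test_that("feature matrices round-trip through the TSV container", {
  set.seed(14)
  fix <- make_random_vcf(tempfile(fileext = ".vcf"), n = 4, v = 10)
  fm <- build_hashed_matrix(fix$path, k = 8, hash_seed = 5)
  prefix <- tempfile()
  write_feature_matrix(fm, prefix)
  back <- read_feature_matrix(prefix)
  expect_equal(back$values, fm$values)
  expect_equal(back$sample_ids, fm$sample_ids)
  expect_equal(back$hash_seed, 5)
  expect_equal(back$encoder, "hashed")
})

test_that("empty streams are an input error", {
  gt <- matrix("0/1", 1, 1)
  vcf <- make_vcf(tempfile(fileext = ".vcf"), "1", 10, "AT", "A", gt)
  expect_error(build_hashed_matrix(vcf, k = 4), "zero biallelic")
  expect_error(build_categorical_matrix(vcf), "zero biallelic")
})
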