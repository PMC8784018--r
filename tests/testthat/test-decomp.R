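test_that("PC1 separates two exact genotype clusters with opposite signs", {
  vcf <- tempfile(fileext = ".vcf")
  sim <- simulate_inversion_vcf(vcf, n_samples = 40, inversion_freq = 0.5,
                                l = 200, m = 200, chrom_length_bp = 1e6,
                                inversion_start_bp = 2e5,
                                inversion_end_bp = 8e5, seed = 301)
  fm <- build_hashed_matrix(vcf, k = 256)
  scores <- fit_pca(fm, 2)
  hom_std <- sim$truth$genotypes == 0
  hom_inv <- sim$truth$genotypes == 2
  s1 <- scores$coords[hom_std, 1]
  s2 <- scores$coords[hom_inv, 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
})

test_that("whitened components have unit variance", {
  set.seed(6)
  X <- matrix(rnorm(50 * 20), 50, 20) %*% diag(c(10, 5, rep(1, 18)))
  scores <- fit_pca(X, 3)
  expect_equal(unname(apply(scores$coords, 2, var)), rep(1, 3),
               tolerance = 1e-8)
})

test_that("explained variance ratios are normalized and ordered", {
  set.seed(9)
  X <- matrix(rnorm(30 * 8), 30, 8)
  scores <- fit_pca(X, 5)
  evr <- scores$explained_variance_ratio
  expect_true(all(evr >= 0 & evr <= 1))
  expect_lte(sum(evr), 1 + 1e-12)
  expect_true(all(diff(evr) <= 1e-12))
})

test_that("degenerate constant input does not crash and explains nothing", {
  X <- matrix(3, 12, 6)
  scores <- fit_pca(X, 2)
  expect_equal(unname(scores$coords), matrix(0, 12, 2))
  expect_equal(scores$explained_variance_ratio, c(0, 0))
})

test_that("component count beyond min(n, k) is an error", {
  expect_error(fit_pca(matrix(rnorm(12), 4, 3), 4), "exceeds")
})

test_that("PCA is deterministic across repeated fits", {
  set.seed(31)
  X <- matrix(rnorm(40 * 30), 40, 30)
  expect_identical(fit_pca(X, 4), fit_pca(X, 4))
})

test_that("hashed and categorical PCA agree on the top-PC partition", {
  vcf <- tempfile(fileext = ".vcf")
  sim <- simulate_inversion_vcf(vcf, n_samples = 60, l = 300, m = 300,
                                chrom_length_bp = 1e6,
                                inversion_start_bp = 2e5,
                                inversion_end_bp = 8e5, seed = 17)
  s_hash <- fit_pca(build_hashed_matrix(vcf, k = 512), 2)
  s_cat <- fit_pca(build_categorical_matrix(vcf), 2)
  # the karyotype partition is recovered identically from both encoders in
  # the leading PC plane (the hashed encoding is linear in allele dosage,
  # the one-hot encoding arranges the three clusters on a triangle, so the
  # comparison must be rotation/sign invariant): perfect linear separation
  # of the planted genotypes either way
  acc_hash <- genotype_separability(s_hash, sim$truth$genotypes, seed = 1)
  acc_cat <- genotype_separability(s_cat, sim$truth$genotypes, seed = 1)
  expect_equal(acc_hash$accuracy, 1.0)
  expect_equal(acc_cat$accuracy, 1.0)
  # and the two homozygous clusters split along the hashed PC1
  hom_std <- sim$truth$genotypes == 0
  hom_inv <- sim$truth$genotypes == 2
  s1 <- s_hash$coords[, 1]
  expect_true(max(s1[hom_std]) < min(s1[hom_inv]) ||
                max(s1[hom_inv]) < min(s1[hom_std]))
})

test_that("separable planted genotypes are classified perfectly", {
  vcf <- tempfile(fileext = ".vcf")
  sim <- simulate_inversion_vcf(vcf, n_samples = 100, l = 500, m = 500,
                                chrom_length_bp = 2e6,
                                inversion_start_bp = 5e5,
                                inversion_end_bp = 1.5e6, seed = 23)
  fm <- build_hashed_matrix(vcf, k = 512)
  scores <- fit_pca(fm, 2)
  res <- genotype_separability(scores, sim$truth$genotypes, seed = 4)
  expect_equal(res$accuracy, 1.0)
  expect_equal(res$n_train + res$n_test, 100)
})

test_that("permuted labels score near the majority-class frequency", {
  set.seed(77)
  n <- 120
  coords <- cbind(rnorm(n), rnorm(n))
  scores <- structure(list(coords = coords,
                           explained_variance_ratio = c(0.5, 0.3), c = 2L),
                      class = "pc_scores")
  labels <- rep(c(0, 1), c(72, 48))  # majority frequency 0.6
  accs <- vapply(1:50, function(i) {
    genotype_separability(scores, sample(labels), seed = i)$accuracy
  }, 0)
  # each test set holds 30 samples; the mean accuracy of a signal-free
  # classifier should sit within binomial error of the majority rate
  se <- sqrt(0.6 * 0.4 / (50 * 30))
  expect_lt(abs(mean(accs) - 0.6), 5 * se + 0.02)
})

test_that("single-member classes are a stratification error", {
  scores <- structure(list(coords = cbind(rnorm(5), rnorm(5)),
                           explained_variance_ratio = c(0.5, 0.2), c = 2L),
                      class = "pc_scores")
  expect_error(genotype_separability(scores, c(0, 0, 0, 0, 1), seed = 1),
               "stratification error")
  expect_error(genotype_separability(scores, rep(0, 5), seed = 1),
               "2 classes")
})

test_that("score tables round-trip through TSV", {
  set.seed(2)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("S%02d", 1:20), NULL))
  scores <- fit_pca(X, 3)
  path <- tempfile(fileext = ".tsv")
  write_scores(scores, path)
  back <- read_scores(path)
  expect_equal(back$coords, scores$coords, tolerance = 1e-10)
})
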