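## PCA on the feature matrix, and a supervised check that inversion
## karyotypes are separable in the leading PC plane.

#' Principal component analysis of a feature matrix
#'
#' Exact (SVD-based) PCA of the centered matrix; scores are whitened, i.e.
#' rescaled so each retained component has unit sample variance, matching
#' the convention of whitened PCA transforms in common ML libraries.
#' Components with zero variance are left at zero rather than divided out.
#'
#' @param x a `feature_matrix` or a plain numeric matrix (samples in rows)
#' @param n_components number of components to retain (default 10, capped
#'   at `min(n, k)`; exceeding the cap is an error)
#' @return an object of class `pc_scores`: list with `coords` (n x c
#'   whitened score matrix), `explained_variance_ratio` (length c) and `c`
#' @export
fit_pca <- function(x, n_components = 10L) {
  X <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (!all(is.finite(X))) stop("input error: feature matrix must be finite")
  n <- nrow(X)
  c_req <- as.integer(n_components)
  if (is.na(c_req) || c_req < 1L)
    stop("parameter error: n_components must be >= 1")
  if (c_req > min(dim(X)))
    stop("parameter error: n_components exceeds min(n, k) = ", min(dim(X)))
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  sdev <- pr$sdev
  total_var <- sum(sdev^2)
  evr_all <- if (total_var > 0) sdev^2 / total_var else rep(0, length(sdev))
  c_avail <- ncol(pr$x)
  c_use <- min(c_req, c_avail)
  coords <- pr$x[, seq_len(c_use), drop = FALSE]
  if (c_use < c_req)   # rank-deficient: pad zero-variance components
    coords <- cbind(coords, matrix(0, n, c_req - c_use))
  sd_c <- c(sdev[seq_len(c_use)], rep(0, c_req - c_use))
  nonzero <- sd_c > 0
  coords[, nonzero] <- sweep(coords[, nonzero, drop = FALSE], 2L,
                             sd_c[nonzero], "/")
  evr <- c(evr_all[seq_len(c_use)], rep(0, c_req - c_use))
  rownames(coords) <- rownames(X)
  colnames(coords) <- paste0("PC", seq_len(c_req))
  structure(list(coords = coords, explained_variance_ratio = evr,
                 c = c_req), class = "pc_scores")
}

#' @export
print.pc_scores <- function(x, ...) {
  cat("<pc_scores>", nrow(x$coords), "samples x", x$c, "components;",
      "explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Write PC scores as TSV
#' @param scores a `pc_scores` object
#' @param path output TSV path (columns `sample_id`, `PC1` ... `PCc`)
#' @return `path`, invisibly
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(sample_id = rownames(scores$coords), scores$coords,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read PC scores written by [write_scores()]
#' @param path TSV path
#' @return a `pc_scores` object (explained variance ratio unavailable: NA)
#' @export
read_scores <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  coords <- as.matrix(df[, -1L, drop = FALSE])
  rownames(coords) <- df[[1L]]
  structure(list(coords = coords,
                 explained_variance_ratio = rep(NA_real_, ncol(coords)),
                 c = ncol(coords)), class = "pc_scores")
}

#' Held-out accuracy of predicting inversion genotypes from two PCs
#'
#' Splits the samples into stratified train/test sets, fits a multinomial
#' logistic regression on the first two PC coordinates only, and reports
#' test-set accuracy.  Used as an evaluation device: accuracy 1.0 means the
#' karyotype classes are linearly separable in the PC1/PC2 plane.
#'
#' @param scores a `pc_scores` object with `c >= 2`
#' @param labels per-sample inversion genotype labels (factor or vector);
#'   at least two classes, each with at least two members
#' @param seed RNG seed for the split
#' @param test_fraction held-out fraction (default 0.25), stratified per class
#' @return list with `accuracy`, `n_train`, `n_test`, `seed`
#' @export
genotype_separability <- function(scores, labels, seed = 1L,
                                  test_fraction = 0.25) {
  stopifnot(inherits(scores, "pc_scores"))
  if (scores$c < 2L) stop("input error: need at least 2 PCs")
  y <- factor(labels)
  n <- nrow(scores$coords)
  if (length(y) != n)
    stop("input error: labels length does not match sample count")
  counts <- table(y)
  if (length(counts) < 2L)
    stop("input error: labels must contain at least 2 classes")
  if (any(counts < 2L))
    stop("stratification error: every class needs >= 2 members; class \"",
         names(counts)[counts < 2L][1L], "\" has ", min(counts))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("parameter error: test_fraction must be in (0, 1)")

  test_idx <- integer()
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (cl in names(counts)) {
    members <- which(y == cl)
    n_test <- max(1L, min(length(members) - 1L,
                          round(test_fraction * length(members))))
    test_idx <- c(test_idx, sample(members, n_test))
  }
  train_idx <- setdiff(seq_len(n), test_idx)

  df <- data.frame(PC1 = scores$coords[, 1L], PC2 = scores$coords[, 2L],
                   y = y)
  fit <- nnet::multinom(y ~ PC1 + PC2, data = df[train_idx, ],
                        trace = FALSE, maxit = 500)
  pred <- predict(fit, newdata = df[test_idx, ])
  acc <- mean(pred == y[test_idx])
  list(accuracy = acc, n_train = length(train_idx),
       n_test = length(test_idx), seed = seed)
}
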