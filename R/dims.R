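## Johnson-Lindenstrauss heuristic for the hashed dimensionality.
##
## Feature hashing acts like a crude random projection, so the JL lemma
## gives a usable upper bound on how many hashed columns preserve the
## pairwise distance structure between samples to relative distortion
## epsilon.  For an inversion occupying l "linked" SNPs among m background
## SNPs, distortions below l/m cannot erase the between-karyotype distance
## gap, which fixes a usable epsilon.

#' Strict upper bound on the admissible JL distortion
#'
#' For `l` inversion-linked SNPs and `m` background SNPs (counts or spans in
#' the same units), the distance gap between inversion karyotypes survives
#' any projection with relative distortion strictly below `l / m`.
#'
#' @param l inversion-linked SNP count or genomic span (> 0)
#' @param m background SNP count or span, same units (> 0)
#' @return the bound `l / m`; choose epsilon strictly below it (and below 1)
#' @export
#' @examples
#' epsilon_bound(7.8, 53.7)
epsilon_bound <- function(l, m) {
  if (any(!is.finite(l)) || any(!is.finite(m)) || any(l <= 0) || any(m <= 0))
    stop("parameter error: l and m must be positive")
  l / m
}

#' Pick a usable epsilon strictly below the l/m bound
#'
#' @inheritParams epsilon_bound
#' @param delta fractional backoff below the bound (default 0.01)
#' @return `min(l/m, 0.999) * (1 - delta)`
#' @export
suggest_epsilon <- function(l, m, delta = 0.01) {
  if (delta <= 0 || delta >= 1) stop("parameter error: delta must be in (0,1)")
  pmin(epsilon_bound(l, m), 0.999) * (1 - delta)
}

#' Minimum hashed dimensionality from the JL lemma
#'
#' Evaluates `4 * ln(n) / (eps^2/2 - eps^3/3)` and truncates toward zero.
#' The natural logarithm and the truncation are the conventions that this
#' package standardizes on (a strict reading of the lower bound would round
#' up; the truncated value differs by at most one column and is what the
#' package reports).
#'
#' @param n number of samples (>= 2)
#' @param epsilon distortion bound in (0, 1); see [epsilon_bound()]
#' @return minimal integer number of hashed columns (>= 1)
#' @export
#' @examples
#' min_dimensions(198, 0.1)
min_dimensions <- function(n, epsilon) {
  if (any(!is.finite(n)) || any(n < 2))
    stop("parameter error: n must be >= 2")
  if (any(!is.finite(epsilon)) || any(epsilon <= 0) || any(epsilon >= 1))
    stop("parameter error: epsilon must be in (0, 1)")
  raw <- 4 * log(n) / (epsilon^2 / 2 - epsilon^3 / 3)
  pmax(1L, as.integer(trunc(raw)))
}

#' Suggest the hashed dimensionality from sample count and inversion extent
#'
#' Convenience wrapper: derives epsilon from `l` and `m` with
#' [suggest_epsilon()] and applies [min_dimensions()].
#'
#' @inheritParams min_dimensions
#' @inheritParams suggest_epsilon
#' @return list with `epsilon` and `k`
#' @export
suggest_dimensions <- function(n, l, m, delta = 0.01) {
  eps <- suggest_epsilon(l, m, delta)
  list(epsilon = eps, k = min_dimensions(n, eps))
}
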