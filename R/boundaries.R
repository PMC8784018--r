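## Inversion localization: Bonferroni-flag the per-SNP p-values, tile the
## chromosome with fixed windows, test each window for enrichment of
## significant SNPs with a one-sided exact binomial test, and call the
## inversion from the centers of the extreme significant windows.

#' Bonferroni flags for per-SNP significance
#'
#' @param pvalues per-SNP p-values (or an `assoc_records` data.frame)
#' @param snp_alpha family-wise error level (default 0.01)
#' @return logical vector: `pvalue < snp_alpha / num_snps` (strict)
#' @export
flag_significant_snps <- function(pvalues, snp_alpha = 0.01) {
  if (inherits(pvalues, "data.frame")) pvalues <- pvalues$pvalue
  if (length(pvalues) == 0L) stop("input error: no p-values")
  if (snp_alpha <= 0 || snp_alpha >= 1)
    stop("parameter error: snp_alpha must be in (0, 1)")
  pvalues < snp_alpha / length(pvalues)
}

#' Windowed binomial enrichment test of significant-SNP fractions
#'
#' The chromosome `[0, chrom_extent)` is tiled with non-overlapping windows
#' of `window_size` bp anchored at 0.  The expected probability that a SNP
#' is significant is the chromosome-wide significant fraction `p0`.  Each
#' window is scored with the one-sided exact binomial tail
#' `P[X >= n_significant]`, `X ~ Binomial(n_snps, p0)`; windows with no
#' SNPs or no significant SNPs receive p = 1.
#'
#' @param positions sorted 1-based bp positions of the scanned SNPs
#' @param flags logical significance flags aligned with `positions`
#' @param window_size window width in bp (default 10000)
#' @param chrom_extent chromosome length in bp; defaults to the largest SNP
#'   position rounded up to a window multiple
#' @return data.frame of class `window_results` with columns `index`
#'   (0-based), `start`, `end`, `n_snps`, `n_significant`, `pvalue`, and
#'   attributes `p0`, `window_size`, `num_windows`
#' @export
test_windows <- function(positions, flags, window_size = 10000L,
                         chrom_extent = NULL) {
  if (length(positions) != length(flags))
    stop("input error: positions and flags lengths differ")
  if (is.unsorted(positions))
    stop("input error: positions must be sorted ascending")
  if (window_size < 1) stop("parameter error: window_size must be >= 1")
  if (is.null(chrom_extent))   # smallest window multiple strictly covering
    chrom_extent <- (max(positions) %/% window_size + 1) * window_size
  num_windows <- as.integer(ceiling(chrom_extent / window_size))
  idx <- as.integer(positions %/% window_size)      # 0-based window index
  if (any(idx >= num_windows))
    stop("input error: SNP positions exceed chrom_extent")
  n_snps <- tabulate(idx + 1L, nbins = num_windows)
  n_sig <- tabulate((idx + 1L)[flags], nbins = num_windows)
  p0 <- sum(flags) / length(flags)
  if (p0 == 0)
    warning("no significant SNPs on the chromosome; all window p-values are 1")
  pv <- rep(1, num_windows)
  testable <- n_snps > 0L & n_sig > 0L & p0 > 0
  pv[testable] <- stats::pbinom(n_sig[testable] - 1L, n_snps[testable], p0,
                                lower.tail = FALSE)
  res <- data.frame(index = seq_len(num_windows) - 1L,
                    start = (seq_len(num_windows) - 1L) * window_size,
                    end = seq_len(num_windows) * window_size,
                    n_snps = n_snps, n_significant = n_sig, pvalue = pv)
  attr(res, "p0") <- p0
  attr(res, "window_size") <- window_size
  attr(res, "num_windows") <- num_windows
  class(res) <- c("window_results", "data.frame")
  res
}

#' Call inversion boundaries from window enrichment results
#'
#' A window is significant when its binomial p-value is strictly below
#' `window_alpha / num_windows`, where `num_windows` counts every tiled
#' window (empty windows carry p = 1 and belong to the tested family).
#' The call spans the centers of the left-most and right-most significant
#' windows.
#'
#' @param windows a `window_results` data.frame from [test_windows()]
#' @param window_alpha family-wise error level for windows (default 0.0001)
#' @param chrom chromosome name attached to the call (optional)
#' @return an `inversion_call` (list with `chrom`, `start_bp`, `end_bp`,
#'   `n_significant_windows`) or `NULL` when no window is significant
#' @export
call_boundaries <- function(windows, window_alpha = 0.0001, chrom = NA) {
  stopifnot(inherits(windows, "window_results"))
  if (window_alpha <= 0 || window_alpha >= 1)
    stop("parameter error: window_alpha must be in (0, 1)")
  num_windows <- attr(windows, "num_windows")
  w <- attr(windows, "window_size")
  sig <- which(windows$pvalue < window_alpha / num_windows)
  if (length(sig) == 0L) return(NULL)
  centers <- windows$start[sig] + w / 2
  structure(list(chrom = chrom, start_bp = min(centers),
                 end_bp = max(centers),
                 n_significant_windows = length(sig)),
            class = "inversion_call")
}

#' @export
print.inversion_call <- function(x, ...) {
  cat(sprintf("<inversion_call> %s:%.3f-%.3f Mb (%d significant windows)\n",
              x$chrom, x$start_bp / 1e6, x$end_bp / 1e6,
              x$n_significant_windows))
  invisible(x)
}

#' Localize an inversion from a Manhattan table
#'
#' Convenience wrapper: [flag_significant_snps()] -> [test_windows()] ->
#' [call_boundaries()].
#'
#' @param records an `assoc_records` data.frame (single chromosome)
#' @param snp_alpha per-SNP family error level (default 0.01)
#' @param window_alpha per-window family error level (default 0.0001)
#' @param window_size window width in bp (default 10000)
#' @param chrom_extent chromosome length in bp (default: inferred)
#' @return list with `call` (an `inversion_call` or NULL), `windows`,
#'   `flags`
#' @export
localize_inversion <- function(records, snp_alpha = 0.01,
                               window_alpha = 0.0001, window_size = 10000L,
                               chrom_extent = NULL) {
  records <- records[order(records$pos), , drop = FALSE]
  flags <- flag_significant_snps(records$pvalue, snp_alpha)
  windows <- test_windows(records$pos, flags, window_size, chrom_extent)
  call <- call_boundaries(windows, window_alpha,
                          chrom = unique(records$chrom)[1L])
  list(call = call, windows = windows, flags = flags)
}

#' Write an inversion call as BED (0-based half-open)
#' @param call an `inversion_call`
#' @param path output BED path
#' @return `path`, invisibly
#' @export
write_call_bed <- function(call, path) {
  stopifnot(inherits(call, "inversion_call"))
  df <- data.frame(chrom = call$chrom,
                   start = format(call$start_bp, scientific = FALSE),
                   end = format(call$end_bp, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
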