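## Sorensen-Dice interval overlap between predicted and known inversions.
##
## Convention: endpoints are first rounded to the nearest 0.1 Mb (half away
## from zero), lengths are continuous interval lengths of the rounded
## intervals, DSC = 2|P on T| / (|P| + |T|).  Percentages are reported with
## one decimal, round-half-up.

# round-half-up at `digits` decimals (base round() is half-to-even)
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' A genomic interval in Mb
#'
#' @param chrom chromosome name
#' @param start_mb,end_mb interval endpoints in Mb (`start_mb <= end_mb`)
#' @return an object of class `genomic_interval`
#' @export
genomic_interval <- function(chrom, start_mb, end_mb) {
  if (!is.finite(start_mb) || !is.finite(end_mb) || start_mb > end_mb)
    stop("input error: need finite start_mb <= end_mb")
  structure(list(chrom = chrom, start_mb = start_mb, end_mb = end_mb),
            class = "genomic_interval")
}

as_interval_mb <- function(x) {
  if (inherits(x, "genomic_interval")) return(x)
  if (inherits(x, "inversion_call"))
    return(genomic_interval(x$chrom, x$start_bp / 1e6, x$end_bp / 1e6))
  if (is.numeric(x) && length(x) == 2L)
    return(genomic_interval(NA, x[1L], x[2L]))
  stop("input error: cannot interpret interval of class ", class(x)[1L])
}

#' Sorensen-Dice overlap of two genomic intervals
#'
#' @param pred predicted interval: a `genomic_interval`, an
#'   `inversion_call`, or a numeric `c(start_mb, end_mb)`
#' @param truth known interval, same forms
#' @return DSC in `[0, 1]`: endpoints rounded to 0.1 Mb, continuous
#'   lengths; 0 for an empty intersection, 1 for identical rounded
#'   intervals
#' @export
#' @examples
#' dice_overlap(c(0.5, 14.3), c(2.2, 13.2))  # 0.887...
dice_overlap <- function(pred, truth) {
  P <- as_interval_mb(pred)
  T_ <- as_interval_mb(truth)
  if (!is.na(P$chrom) && !is.na(T_$chrom) && P$chrom != T_$chrom)
    stop("input error: chromosome mismatch: ", P$chrom, " vs ", T_$chrom)
  p <- round_half_up(c(P$start_mb, P$end_mb), 1L)
  t <- round_half_up(c(T_$start_mb, T_$end_mb), 1L)
  inter <- max(0, min(p[2L], t[2L]) - max(p[1L], t[1L]))
  denom <- (p[2L] - p[1L]) + (t[2L] - t[1L])
  if (denom == 0) return(as.numeric(inter >= 0 && all(p == t)))
  2 * inter / denom
}

#' Format a DSC as a percentage with one decimal (round-half-up)
#' @param dsc a Dice coefficient in `[0, 1]`
#' @return numeric percentage with one decimal
#' @export
dice_percent <- function(dsc) {
  round_half_up(100 * dsc, 1L)
}

#' Mean Dice overlap over interval pairs
#'
#' @param pairs a list of two-element lists/vectors `(pred, truth)` (any
#'   forms accepted by [dice_overlap()]), or a numeric vector of
#'   already-computed DSC values
#' @return arithmetic mean DSC
#' @export
average_overlap <- function(pairs) {
  if (length(pairs) == 0L) stop("input error: no interval pairs")
  if (is.numeric(pairs)) return(mean(pairs))
  mean(vapply(pairs, function(p) dice_overlap(p[[1L]], p[[2L]]), 0))
}

#' Read intervals from BED (bp) or two-column Mb TSV
#'
#' BED input (`.bed`, 0-based half-open, bp) is converted to Mb; any other
#' extension is read as a headerless TSV of `chrom`, `start_mb`, `end_mb`.
#'
#' @param path input path
#' @return list of `genomic_interval`s
#' @export
read_intervals <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  scale <- if (grepl("\\.bed$", path, ignore.case = TRUE)) 1e6 else 1
  lapply(seq_len(nrow(df)), function(i)
    genomic_interval(df[i, 1L], df[i, 2L] / scale, df[i, 3L] / scale))
}
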