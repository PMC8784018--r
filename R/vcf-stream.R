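## Streaming VCF access.
##
## The feature matrices downstream are sized by the number of samples and
## hashed columns only, so the reader must never hold more than one batch of
## variant lines in memory.  Plain-text and gzip/bgzip-compressed VCFs are
## both supported through a (gz)file connection.

GT_CODE <- c(
  "0/0" = 0L, "0|0" = 0L,
  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L
)

#' Read the sample identifiers from a VCF header
#'
#' @param vcf path to a VCF file (optionally gzip/bgzip compressed)
#' @return character vector of sample identifiers in file (column) order.
#'   Their count defines the row count of every downstream feature matrix.
#' @export
#' @examples
#' vcf <- tempfile(fileext = ".vcf")
#' sim <- simulate_inversion_vcf(vcf, n_samples = 4, l = 5, m = 5,
#'                               chrom_length_bp = 1e5,
#'                               inversion_start_bp = 2e4,
#'                               inversion_end_bp = 8e4, seed = 1)
#' vcf_samples(vcf)
vcf_samples <- function(vcf) {
  con <- open_vcf_connection(vcf)
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L)
      stop("VCF format error: no #CHROM header line found in ", vcf)
    if (startsWith(line, "#CHROM")) {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (length(fields) < 10L)
        stop("VCF input error: file has no sample columns: ", vcf)
      return(fields[-(1:9)])
    }
    if (!startsWith(line, "##") && !startsWith(line, "#CHROM"))
      stop("VCF format error: data line encountered before #CHROM header")
  }
}

open_vcf_connection <- function(vcf) {
  if (!file.exists(vcf)) stop("VCF input error: no such file: ", vcf)
  con <- gzfile(vcf, open = "rt")  # transparently handles plain text too
  con
}

#' Open a batched reader over the biallelic SNPs of a VCF file
#'
#' Returns a reader handle that yields `VariantBatch` objects of at most
#' `batch_size` records.  Multi-allelic records, indels, and other non-SNP
#' records are skipped and counted; only the current batch of lines is ever
#' resident in memory.
#'
#' Genotype calls are coded `0` (homozygous reference), `1` (heterozygous),
#' `2` (homozygous alternate) and `NA` (unknown).  `/` and `|` separators
#' are treated identically, and any call containing `.` in either haplotype
#' (including half-calls such as `0/.`) is coded `NA`.
#'
#' @param vcf path to a VCF file
#' @param batch_size maximum number of SNP records per batch (default 10000)
#' @param chroms optional character vector restricting records to these
#'   chromosome names
#' @return an object of class `vcf_reader` with methods accessed through
#'   [read_batch()], [reader_stats()] and [close_reader()]
#' @export
vcf_reader <- function(vcf, batch_size = 10000L, chroms = NULL) {
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L)
    stop("parameter error: batch_size must be >= 1")
  samples <- vcf_samples(vcf)
  con <- open_vcf_connection(vcf)
  # skip header; header lines re-read so the connection points at data
  n_header <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    n_header <- n_header + 1L
    if (startsWith(line, "#CHROM")) break
  }
  env <- new.env(parent = emptyenv())
  env$con <- con
  env$samples <- samples
  env$batch_size <- batch_size
  env$chroms <- chroms
  env$line_no <- n_header      # last consumed physical line
  env$n_yielded <- 0L
  env$n_skipped <- 0L
  env$n_data_lines <- 0L
  env$open <- TRUE
  structure(env, class = "vcf_reader")
}

#' Read the next batch of biallelic SNP records
#'
#' @param reader a [vcf_reader()] handle
#' @return a `variant_batch` (list with `chrom`, `pos`, `ref`, `alt` vectors
#'   and an integer genotype matrix `geno` of dimension records x samples),
#'   or `NULL` at end of file.  A returned batch always holds at least one
#'   record.
#' @export
read_batch <- function(reader) {
  stopifnot(inherits(reader, "vcf_reader"))
  if (!reader$open) return(NULL)
  n_samples <- length(reader$samples)
  repeat {
    lines <- readLines(reader$con, n = reader$batch_size)
    if (length(lines) == 0L) {
      close_reader(reader)
      return(NULL)
    }
    first_line <- reader$line_no + 1L
    reader$line_no <- reader$line_no + length(lines)
    reader$n_data_lines <- reader$n_data_lines + length(lines)
    batch <- parse_vcf_lines(lines, n_samples, first_line, reader$chroms)
    reader$n_skipped <- reader$n_skipped + batch$n_skipped
    if (length(batch$pos) > 0L) {
      reader$n_yielded <- reader$n_yielded + length(batch$pos)
      return(batch)
    }
    # whole batch skipped (e.g. filtered chromosome); keep reading
  }
}

#' Close a VCF reader
#' @param reader a [vcf_reader()] handle
#' @return the reader, invisibly
#' @export
close_reader <- function(reader) {
  if (reader$open) {
    close(reader$con)
    reader$open <- FALSE
  }
  invisible(reader)
}

#' Skip and yield statistics of a reader
#' @param reader a [vcf_reader()] handle
#' @return list with `n_yielded`, `n_skipped`, `n_data_lines`, `samples`
#' @export
reader_stats <- function(reader) {
  list(n_yielded = reader$n_yielded, n_skipped = reader$n_skipped,
       n_data_lines = reader$n_data_lines, samples = reader$samples)
}

#' @export
print.vcf_reader <- function(x, ...) {
  cat("<vcf_reader>", length(x$samples), "samples;",
      x$n_yielded, "SNPs yielded,", x$n_skipped, "records skipped\n")
  invisible(x)
}

BASES <- c("A", "C", "G", "T")

parse_vcf_lines <- function(lines, n_samples, first_line, chroms = NULL) {
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  expected <- 9L + n_samples
  if (any(nf != expected)) {
    bad <- which(nf != expected)[1L]
    stop("VCF format error at line ", first_line + bad - 1L, ": expected ",
         expected, " tab-separated fields, found ", nf[bad])
  }
  m <- matrix(unlist(fields, use.names = FALSE), nrow = expected)
  chrom <- m[1L, ]
  pos <- suppressWarnings(as.integer(m[2L, ]))
  ref <- m[4L, ]
  alt <- m[5L, ]
  fmt <- m[9L, ]
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("VCF format error at line ", first_line + bad - 1L,
         ": POS is not an integer")
  }

  keep <- ref %in% BASES & alt %in% BASES & ref != alt
  if (!is.null(chroms)) keep <- keep & chrom %in% chroms
  n_skipped <- sum(!keep)
  idx <- which(keep)

  if (length(idx) == 0L) {
    return(new_variant_batch(character(), integer(), character(),
                             character(), matrix(integer(), 0L, n_samples),
                             n_skipped))
  }

  gt_strings <- m[10:expected, idx, drop = FALSE]  # samples x records
  fmt_kept <- fmt[idx]
  plain <- fmt_kept == "GT"
  leading <- startsWith(fmt_kept, "GT:")
  if (!all(plain | leading)) {
    # GT somewhere else in FORMAT (or absent): locate per record
    other <- which(!(plain | leading))
    for (j in other) {
      keys <- strsplit(fmt_kept[j], ":", fixed = TRUE)[[1L]]
      gi <- match("GT", keys)
      if (is.na(gi))
        stop("VCF format error at line ", first_line + idx[j] - 1L,
             ": no GT key in FORMAT")
      parts <- strsplit(gt_strings[, j], ":", fixed = TRUE)
      gt_strings[, j] <- vapply(parts, `[`, "", gi)
    }
  }
  if (any(leading))
    gt_strings[, leading] <- sub(":.*", "", gt_strings[, leading])

  code <- GT_CODE[gt_strings]
  unknown <- is.na(code)
  if (any(unknown)) {
    has_dot <- grepl(".", gt_strings[unknown], fixed = TRUE)
    if (!all(has_dot)) {
      bad_flat <- which(unknown)[which(!has_dot)[1L]]
      rec <- ((bad_flat - 1L) %/% n_samples) + 1L
      stop("VCF format error at line ", first_line + idx[rec] - 1L,
           ": unrecognized GT call \"",
           gt_strings[unknown][which(!has_dot)[1L]], "\"")
    }
  }
  geno <- matrix(unname(code), nrow = length(idx), ncol = n_samples,
                 byrow = TRUE)
  new_variant_batch(chrom[idx], pos[idx], ref[idx], alt[idx], geno, n_skipped)
}

new_variant_batch <- function(chrom, pos, ref, alt, geno, n_skipped = 0L) {
  structure(list(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 geno = geno, n_skipped = n_skipped),
            class = "variant_batch")
}

#' Apply a function to every batch of a VCF stream
#'
#' Convenience driver used by the matrix builders and the association scan:
#' opens a reader, applies `fn` to each `variant_batch`, closes the reader,
#' and returns the stream statistics.
#'
#' @param vcf path to a VCF file
#' @param fn function of one argument (a `variant_batch`)
#' @param batch_size records per batch
#' @param chroms optional chromosome filter
#' @return [reader_stats()] of the completed stream, invisibly
#' @export
stream_variants <- function(vcf, fn, batch_size = 10000L, chroms = NULL) {
  rdr <- vcf_reader(vcf, batch_size = batch_size, chroms = chroms)
  on.exit(close_reader(rdr))
  repeat {
    b <- read_batch(rdr)
    if (is.null(b)) break
    fn(b)
  }
  invisible(reader_stats(rdr))
}
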