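# Fixture builders: hand-written VCFs assembled in code, never stored.

# Write a VCF from explicit fields.  `gt` is a v x n character matrix of
# genotype call strings ("0/0", "0|1", "./.", ...); `raw_lines` appends
# arbitrary extra data lines verbatim (for malformed-input tests).
make_vcf <- function(path, chrom, pos, ref, alt, gt,
                     samples = sprintf("S%d", seq_len(ncol(gt))),
                     format = "GT", qual = ".", raw_lines = NULL) {
  gt <- matrix(as.character(gt), nrow = length(pos))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- character(length(pos))
  for (i in seq_along(pos)) {
    body[i] <- paste(c(chrom[min(i, length(chrom))], pos[i], ".", ref[i],
                       alt[i], qual, "PASS", ".",
                       format[min(i, length(format))], gt[i, ]),
                     collapse = "\t")
  }
  writeLines(c(header, body, raw_lines), path)
  path
}

# A random small biallelic VCF; returns list(path, geno) with the integer
# genotype codes (0/1/2/NA) actually written.
make_random_vcf <- function(path, n = 10, v = 50, chrom = "1",
                            missing_rate = 0.05) {
  pos <- sort(sample.int(1e6, v))
  pick <- sample.int(4, v, replace = TRUE)
  ref <- c("A", "C", "G", "T")[pick]
  alt <- c("G", "T", "A", "C")[pick]
  geno <- matrix(sample(0:2, v * n, replace = TRUE), nrow = v)
  geno[matrix(runif(v * n) < missing_rate, nrow = v)] <- NA
  gt <- matrix("./.", v, n)
  gt[!is.na(geno)] <- c("0/0", "0/1", "1/1")[geno[!is.na(geno)] + 1]
  make_vcf(path, chrom, pos, ref, alt, gt)
  list(path = path, chrom = chrom, pos = pos, ref = ref, alt = alt,
       geno = geno)
}

# Collect every record of a VCF stream into one batch-like list.
collect_stream <- function(vcf, batch_size = 10000, chroms = NULL) {
  out <- list(chrom = character(), pos = integer(), ref = character(),
              alt = character(), geno = NULL)
  stats <- stream_variants(vcf, function(b) {
    out$chrom <<- c(out$chrom, b$chrom)
    out$pos <<- c(out$pos, b$pos)
    out$ref <<- c(out$ref, b$ref)
    out$alt <<- c(out$alt, b$alt)
    out$geno <<- rbind(out$geno, b$geno)
  }, batch_size = batch_size, chroms = chroms)
  out$stats <- stats
  out
}
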