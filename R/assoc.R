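## Per-SNP association between genotype classes and one principal component.
##
## For each SNP the selected PC coordinates are partitioned into groups by
## genotype class (HOM_REF / HET / HOM_ALT); samples with unknown genotype
## are excluded; a one-way ANOVA F-test p-value is computed.  SNPs are
## streamed so memory stays bounded by one batch.  The F statistic is
## evaluated in closed form, vectorized over the batch.

PVALUE_FLOOR <- 1e-300   # clamp before -log10 so records stay finite

# Vectorized one-way ANOVA of y (length n) against genotype codes 0/1/2
# with NA exclusion.  G is a v x n integer matrix.  Returns p-values.
# Degenerate SNPs -- fewer than 2 non-empty groups, or no residual degrees
# of freedom -- receive p = 1 so downstream test counts stay well defined.
anova_batch_pvalues <- function(G, y) {
  y <- as.numeric(y)
  y2 <- y^2
  N <- 0; S <- 0; Q <- 0; SSB_acc <- 0; n_groups <- 0
  for (g in 0:2) {
    ind <- (!is.na(G)) & (G == g)
    mode(ind) <- "numeric"
    Ng <- as.vector(ind %*% rep(1, length(y)))
    Sg <- as.vector(ind %*% y)
    Qg <- as.vector(ind %*% y2)
    nonempty <- Ng > 0
    n_groups <- n_groups + nonempty
    N <- N + Ng; S <- S + Sg; Q <- Q + Qg
    SSB_acc <- SSB_acc + ifelse(nonempty, Sg^2 / pmax(Ng, 1), 0)
  }
  p <- rep(1, nrow(G))
  df1 <- n_groups - 1
  df2 <- N - n_groups
  valid <- n_groups >= 2 & df2 >= 1
  if (any(valid)) {
    SSB <- SSB_acc - S^2 / pmax(N, 1)
    SST <- Q - S^2 / pmax(N, 1)
    SSW <- pmax(SST - SSB, 0)
    Fstat <- (SSB / df1) / (SSW / df2)
    pv <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    # zero within-group variance with real between-group spread: p -> 0;
    # zero between-group spread (possibly with zero residual too): p = 1
    pv[valid & SSW == 0 & SSB > 0] <- 0
    pv[valid & SSB <= 0] <- 1
    p[valid] <- pv[valid]
  }
  p
}

#' Streaming single-SNP ANOVA scan against one principal component
#'
#' @param vcf path to a VCF file; sample columns must match the scores
#' @param scores a `pc_scores` object (see [fit_pca()])
#' @param component 1-based index of the PC to test (default 1)
#' @param batch_size variants per streamed batch
#' @param chroms optional chromosome filter
#' @return a data.frame of class `assoc_records` with columns `chrom`,
#'   `pos`, `pvalue`, `neglog10p` (p-values clamped at 1e-300 before the
#'   log transform)
#' @export
snp_pc_scan <- function(vcf, scores, component = 1L, batch_size = 10000L,
                        chroms = NULL) {
  stopifnot(inherits(scores, "pc_scores"))
  component <- as.integer(component)
  if (is.na(component) || component < 1L || component > scores$c)
    stop("parameter error: component must be in 1..", scores$c)
  samples <- vcf_samples(vcf)
  if (length(samples) != nrow(scores$coords))
    stop("input error: VCF has ", length(samples), " samples but scores have ",
         nrow(scores$coords))
  y <- scores$coords[, component]
  out <- list()
  stream_variants(vcf, function(b) {
    p <- anova_batch_pvalues(b$geno, y)
    out[[length(out) + 1L]] <<- data.frame(chrom = b$chrom, pos = b$pos,
                                           pvalue = p,
                                           stringsAsFactors = FALSE)
  }, batch_size = batch_size, chroms = chroms)
  if (length(out) == 0L)
    stop("input error: VCF stream yielded zero biallelic SNPs")
  rec <- do.call(rbind, out)
  rec$neglog10p <- -log10(pmax(rec$pvalue, PVALUE_FLOOR))
  class(rec) <- c("assoc_records", "data.frame")
  rec
}

#' Write the Manhattan table (and optionally a Manhattan plot)
#'
#' @param records an `assoc_records` data.frame from [snp_pc_scan()]
#' @param path output TSV path; columns `chrom`, `pos`, `pvalue`,
#'   `neglog10p`, sorted by position
#' @param plot_path optional PNG path for a scatter of `-log10(p)` vs
#'   position
#' @return `path`, invisibly
#' @export
write_manhattan <- function(records, path, plot_path = NULL) {
  if (is.null(records) || nrow(records) == 0L)
    stop("input error: empty association record set")
  records <- records[order(records$pos), , drop = FALSE]
  utils::write.table(records[, c("chrom", "pos", "pvalue", "neglog10p")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(plot_path)) {
    grDevices::png(plot_path, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
    graphics::plot(records$pos / 1e6, records$neglog10p, pch = 20,
                   cex = 0.4, col = "steelblue4",
                   xlab = "position (Mb)", ylab = expression(-log[10](p)),
                   main = unique(records$chrom)[1L])
  }
  invisible(path)
}

#' Read a Manhattan table written by [write_manhattan()]
#' @param path TSV path
#' @return an `assoc_records` data.frame
#' @export
read_manhattan <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "integer",
                                          "numeric", "numeric"))
  class(rec) <- c("assoc_records", "data.frame")
  rec
}
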