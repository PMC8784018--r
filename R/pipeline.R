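## End-to-end workflow: feature matrix -> PCA -> PC1 association scan ->
## windowed boundary calling.

#' Run the full inversion detection and localization workflow on one VCF
#'
#' @param vcf path to a VCF file (one chromosome or filtered via `chroms`)
#' @param k hashed dimensionality; `NULL` derives it from the JL heuristic
#'   using `jl_l`/`jl_m`
#' @param encoder `"hashed"` (default) or `"categorical"`
#' @param jl_l,jl_m inversion / background extents for [suggest_dimensions()]
#'   when `k` is NULL
#' @param n_components PCs retained in the decomposition (default 10)
#' @param component PC used for the association scan (default 1)
#' @param hash_seed hash seed for the hashed encoder
#' @param batch_size streamed variants per batch
#' @param snp_alpha,window_alpha,window_size boundary-calling parameters,
#'   see [localize_inversion()]
#' @param chrom_extent chromosome length in bp (default: inferred)
#' @param chroms optional chromosome filter
#' @return list with `matrix_meta`, `scores`, `records`, `windows`,
#'   `flags`, `call` (an `inversion_call` or NULL)
#' @export
run_inversion_scan <- function(vcf, k = NULL, encoder = c("hashed",
                                                          "categorical"),
                               jl_l = NULL, jl_m = NULL,
                               n_components = 10L, component = 1L,
                               hash_seed = 0L, batch_size = 10000L,
                               snp_alpha = 0.01, window_alpha = 0.0001,
                               window_size = 10000L, chrom_extent = NULL,
                               chroms = NULL) {
  encoder <- match.arg(encoder)
  if (encoder == "hashed" && is.null(k)) {
    if (is.null(jl_l) || is.null(jl_m))
      stop("parameter error: supply k, or jl_l and jl_m for the JL heuristic")
    n <- length(vcf_samples(vcf))
    k <- suggest_dimensions(n, jl_l, jl_m)$k
  }
  fm <- if (encoder == "hashed")
    build_hashed_matrix(vcf, k, hash_seed = hash_seed,
                        batch_size = batch_size, chroms = chroms)
  else
    build_categorical_matrix(vcf, batch_size = batch_size, chroms = chroms)
  n_components <- min(n_components, dim(fm$values))
  scores <- fit_pca(fm, n_components)
  records <- snp_pc_scan(vcf, scores, component = component,
                         batch_size = batch_size, chroms = chroms)
  loc <- localize_inversion(records, snp_alpha = snp_alpha,
                            window_alpha = window_alpha,
                            window_size = window_size,
                            chrom_extent = chrom_extent)
  list(matrix_meta = fm[setdiff(names(fm), "values")], scores = scores,
       records = records, windows = loc$windows, flags = loc$flags,
       call = loc$call)
}
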