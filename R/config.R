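#' Analysis configuration
#'
#' Bundles the constants used across the pipeline. Extents are in bp.
#'
#' @param seed Integer seed for all randomised steps.
#' @param n_permutations Rounds for permutation overlap tests (default 1000).
#' @param n_bootstrap Rounds for the accessibility bootstrap (default 100).
#' @param promoter_extension Promoter = TSS extended this far downstream, in
#'   the direction of transcription (default 5000).
#' @param enhancer_flank Enhancers tested as center +/- this flank (default 50).
#' @param peak_flank Binding sites scored over center +/- this flank
#'   (default 250).
#' @param tss_flank Half-width of the TSS accessibility profile (default 1000).
#' @param outlier_linking_threshold Genes with `|linking score|` above this are
#'   dropped as influential outliers before correlation (default 40).
#' @param pseudocount_expression Pseudocount inside the expression score
#'   (default 0.01).
#' @param pseudocount_atac Pseudocount for accessibility ratios and the floor
#'   for log10 of a zero mean signal (default 0.01).
#' @return A list of class `loopstats_config`.
#' @export
run_config <- function(seed = 1L,
                       n_permutations = 1000L,
                       n_bootstrap = 100L,
                       promoter_extension = 5000,
                       enhancer_flank = 50,
                       peak_flank = 250,
                       tss_flank = 1000,
                       outlier_linking_threshold = 40,
                       pseudocount_expression = 0.01,
                       pseudocount_atac = 0.01) {
  cfg <- list(seed = as.integer(seed),
              n_permutations = as.integer(n_permutations),
              n_bootstrap = as.integer(n_bootstrap),
              promoter_extension = promoter_extension,
              enhancer_flank = enhancer_flank,
              peak_flank = peak_flank,
              tss_flank = tss_flank,
              outlier_linking_threshold = outlier_linking_threshold,
              pseudocount_expression = pseudocount_expression,
              pseudocount_atac = pseudocount_atac)
  extents <- c("promoter_extension", "enhancer_flank", "peak_flank", "tss_flank")
  if (any(unlist(cfg[extents]) <= 0)) stop("all extents must be positive")
  if (cfg$pseudocount_expression <= 0 || cfg$pseudocount_atac <= 0) {
    stop("pseudocounts must be positive")
  }
  structure(cfg, class = "loopstats_config")
}

#' Read a configuration from YAML
#'
#' @param path Path to a YAML file with any subset of [run_config()] fields.
#' @return A `loopstats_config` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[intersect(names(vals), names(formals(run_config)))])
}
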