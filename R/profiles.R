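#' Per-bp accessibility log2 fold-change profile around TSS
#'
#' For every offset in `-tss_flank .. tss_flank` (relative to the TSS, strand
#' oriented so positive offsets are downstream of transcription), computes the
#' mean over genes of `log2((ko + pc) / (wt + pc))` of the per-bp track
#' values, `pc = pseudocount_atac`.
#'
#' @param genes Gene tibble.
#' @param track_wt,track_ko Signal track tibbles (wild type / knockout).
#' @param config A [run_config()].
#' @return Tibble with columns `offset` (length `2 * tss_flank + 1`) and
#'   `log2fc`.
#' @export
tss_profile <- function(genes, track_wt, track_ko, config = run_config()) {
  stopifnot(nrow(track_wt) > 0, nrow(track_ko) > 0, nrow(genes) > 0)
  f <- config$tss_flank
  offsets <- seq(-f, f)
  plus <- genes$strand != "-"
  tss <- ifelse(plus, genes$start, genes$end - 1)
  dir <- ifelse(plus, 1, -1)
  pos <- rep(tss, each = length(offsets)) +
    rep(dir, each = length(offsets)) * rep(offsets, times = nrow(genes))
  chrom <- rep(genes$chrom, each = length(offsets))
  pc <- config$pseudocount_atac
  wt <- track_value_at(track_wt, chrom, pos)
  ko <- track_value_at(track_ko, chrom, pos)
  l2 <- log2((ko + pc) / (wt + pc))
  tibble::tibble(offset = offsets,
                 log2fc = as.numeric(rowsum(l2, rep(offsets, times = nrow(genes)),
                                            reorder = TRUE)) / nrow(genes))
}

#' @noRd
gene_bins_profile <- function(gene_row, n_bins, flank_bins, flank_bin_width) {
  s <- gene_row$start; e <- gene_row$end
  w <- floor((e - s) / n_bins)
  # remainder bp go to the 3'-most body bin (rightmost on +, leftmost on -)
  body_edges <- if (gene_row$strand == "-") {
    c(s, e - w * rev(seq_len(n_bins) - 1))
  } else {
    c(s + w * (seq_len(n_bins) - 1), e)
  }
  up <- seq(s - flank_bins * flank_bin_width, s, by = flank_bin_width)
  down <- seq(e, e + flank_bins * flank_bin_width, by = flank_bin_width)
  starts <- c(up[-length(up)], body_edges[-length(body_edges)], down[-length(down)])
  ends <- c(up[-1], body_edges[-1], down[-1])
  idx <- seq_along(starts)
  if (gene_row$strand == "-") idx <- rev(idx)
  tibble::tibble(chrom = gene_row$chrom, start = starts, end = ends,
                 bin = idx)
}

#' Binned accessibility log2 fold-change across scaled gene bodies
#'
#' Gene bodies are split into `n_bins` equal-width bins (remainder bp to the
#' 3'-most body bin) and flanked by `flank_bins` fixed-width bins on each
#' side; bins are ordered 5' to 3' in the direction of transcription. Per bin
#' and gene, `log2((mean ko + pc) / (mean wt + pc))` is computed from the mean
#' track signal over the bin, then averaged over genes. Genes shorter than
#' `n_bins` bp are skipped with a warning; flank bins falling off the
#' chromosome are clipped (dropped if empty).
#'
#' @inheritParams tss_profile
#' @param n_bins Number of gene-body bins (default 20).
#' @param flank_bins Number of fixed-width flank bins per side (default 5).
#' @param flank_bin_width Width of each flank bin in bp (default 500).
#' @param genome Optional genome tibble for clipping flank bins.
#' @return Tibble with `bin` (1 .. `n_bins + 2 * flank_bins`), `region`
#'   (upstream/body/downstream) and `log2fc`.
#' @export
gene_body_profile <- function(genes, track_wt, track_ko, n_bins = 20,
                              flank_bins = 5, flank_bin_width = 500,
                              config = run_config(), genome = NULL) {
  stopifnot(n_bins >= 1)
  short <- genes$end - genes$start < n_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than n_bins skipped")
    genes <- genes[!short, , drop = FALSE]
  }
  bins <- purrr::map_dfr(seq_len(nrow(genes)),
                         function(i) gene_bins_profile(genes[i, ], n_bins,
                                                       flank_bins, flank_bin_width))
  bins$start <- pmax(bins$start, 0)
  if (!is.null(genome)) bins$end <- pmin(bins$end, genome_size_of(genome, bins$chrom))
  keep <- bins$end > bins$start
  bins <- bins[keep, , drop = FALSE]
  pc <- config$pseudocount_atac
  wt <- track_mean(track_wt, bins)
  ko <- track_mean(track_ko, bins)
  bins$l2 <- log2((ko + pc) / (wt + pc))
  total <- n_bins + 2 * flank_bins
  out <- dplyr::summarise(dplyr::group_by(bins, .data$bin),
                          log2fc = mean(.data$l2), .groups = "drop")
  out <- dplyr::left_join(tibble::tibble(bin = seq_len(total)), out, by = "bin")
  out$region <- ifelse(out$bin <= flank_bins, "upstream",
                       ifelse(out$bin <= flank_bins + n_bins, "body", "downstream"))
  out[c("bin", "region", "log2fc")]
}
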