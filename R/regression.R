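#' Seven-bin partition of a gene and its flanks
#'
#' Each gene contributes, in transcription orientation: an upstream bin
#' (TSS -4 kbp to -2 kbp), a promoter bin (-2 kbp to TSS), three equal-width
#' gene-body bins (remainder bp assigned to the 3'-most body bin), and two
#' downstream bins (TTS to +2 kbp and +2 kbp to +4 kbp). Minus-strand genes
#' are mirrored genomically so bin 1 is always the most upstream. Flank bins
#' are clipped at chromosome ends and flagged.
#'
#' @param genes Gene tibble; every gene must be >= 3 bp long.
#' @param genome Optional genome tibble used to clip flank bins.
#' @param flank_bin_width Width of each flank bin (default 2000 bp).
#' @return Tibble with `gene_id`, `bin` (1-7), `chrom, start, end`,
#'   `clipped`.
#' @export
make_gene_bins <- function(genes, genome = NULL, flank_bin_width = 2000) {
  short <- which(genes$end - genes$start < 3)
  if (length(short)) stop("gene(s) shorter than 3 bp at row(s): ",
                          paste(utils::head(short, 5), collapse = ", "))
  n <- nrow(genes)
  s <- genes$start; e <- genes$end; minus <- genes$strand == "-"
  L <- e - s
  w <- floor(L / 3)
  fb <- flank_bin_width
  # genomic edges of the 7 bins, left to right, then bin indices by strand
  edges <- cbind(s - 2 * fb, s - fb, s,
                 ifelse(minus, s + (L - 2 * w), s + w),
                 ifelse(minus, s + (L - w), s + 2 * w),
                 e, e + fb, e + 2 * fb)
  bin_of <- function(col) ifelse(minus, 8 - col, col) # genomic col -> bin rank
  out <- tibble::tibble(
    gene_id = rep(genes$gene_id, each = 7),
    chrom = rep(genes$chrom, each = 7),
    start = as.numeric(t(edges[, 1:7, drop = FALSE])),
    end = as.numeric(t(edges[, 2:8, drop = FALSE])),
    bin = as.integer(t(vapply(1:7, bin_of, numeric(n)))))
  raw_start <- out$start; raw_end <- out$end
  out$start <- pmax(out$start, 0)
  out$end <- pmax(out$end, 0)
  if (!is.null(genome)) {
    size <- genome_size_of(genome, out$chrom)
    out$end <- pmin(out$end, size)
    out$start <- pmin(out$start, out$end)
  }
  out$clipped <- out$start != raw_start | out$end != raw_end
  out[order(match(out$gene_id, genes$gene_id), out$bin), ]
}

#' Binary occupancy of bins by peaks
#'
#' @param bins Bin tibble ([make_gene_bins()]).
#' @param peaks Interval tibble of binding sites.
#' @return `bins` with an `occupied` column: 1 if any peak overlaps the bin by
#'   >= 1 bp, else 0 (zero-width clipped bins are 0).
#' @export
occupancy_bits <- function(bins, peaks) {
  out <- bins
  nonempty <- bins$end > bins$start
  occ <- logical(nrow(bins))
  occ[nonempty] <- overlaps_any(bins[nonempty, , drop = FALSE], peaks)
  out$occupied <- as.integer(occ)
  out
}

#' Accessibility-difference predictor
#'
#' `log10((ko + pc) / (wt + pc)) * log2(total + 1)` with `pc` the
#' accessibility pseudocount; the second factor weights the log ratio by the
#' total signal so that differences at well-covered bins dominate. Its sign
#' equals `sign(ko - wt)` whenever `total > 0`, and the value is 0 when
#' `total = 0`.
#'
#' @param ko_reads,wt_reads Normalised reads per bin (knockout / wild type).
#' @param total_reads Total normalised reads per bin.
#' @param pseudocount Pseudocount (default 0.01).
#' @return Numeric vector.
#' @export
atac_diff <- function(ko_reads, wt_reads, total_reads, pseudocount = 0.01) {
  stopifnot(all(ko_reads >= 0), all(wt_reads >= 0), all(total_reads >= 0))
  log10((ko_reads + pseudocount) / (wt_reads + pseudocount)) *
    log2(total_reads + 1)
}

#' @noRd
enhancer_link_count <- function(genes, loops, enhancers, config) {
  if (nrow(loops) == 0 || nrow(genes) == 0) return(integer(nrow(genes)))
  enh <- enhancer_windows(enhancers, config)
  anch <- loop_anchors(loops)
  n <- nrow(loops)
  enh_hit <- overlaps_any(anch, enh)
  gene_hits <- overlap_pairs(anch, genes)
  if (nrow(gene_hits) == 0) return(integer(nrow(genes)))
  row <- ((gene_hits$query - 1) %% n) + 1
  is_left <- gene_hits$query <= n
  opp_enh <- ifelse(is_left, enh_hit[row + n], enh_hit[row])
  linked <- tibble::tibble(gene = gene_hits$subject, loop = row)[opp_enh, ]
  linked <- dplyr::distinct(linked)
  out <- integer(nrow(genes))
  tab <- table(linked$gene)
  out[as.integer(names(tab))] <- as.integer(tab)
  out
}

#' Assemble the per-gene predictor matrix for the expression-change model
#'
#' One row per gene: seven binary occupancy bits (one per gene bin), seven
#' accessibility-difference values (per-bin mean track signal, total = wt +
#' ko), counts of loops with an anchor on the gene for two structural factors,
#' the count of loops connecting the gene to an enhancer for factor A, counts
#' of over-/under-interacting differential loops, and the `log2fc` response.
#' Genes without an expression record are dropped with a message.
#'
#' @param genes Gene tibble.
#' @param expression Expression tibble.
#' @param peaks Binding-site interval tibble (factor A occupancy).
#' @param satb1_loops,ctcf_loops Structural loop tibbles (factor A / factor B).
#' @param over_loops,under_loops Differential loop tibbles.
#' @param enhancers Enhancer interval tibble.
#' @param track_wt,track_ko Accessibility signal tracks.
#' @param config A [run_config()].
#' @param genome Optional genome tibble; coordinates beyond chromosome ends
#'   are an error (inconsistent builds).
#' @return Predictor tibble.
#' @export
assemble_matrix <- function(genes, expression, peaks, satb1_loops, ctcf_loops,
                            over_loops, under_loops, enhancers,
                            track_wt, track_ko,
                            config = run_config(), genome = NULL) {
  if (!is.null(genome)) {
    validate_intervals(genes, genome)
    validate_intervals(peaks, genome)
    for (l in list(satb1_loops, ctcf_loops, over_loops, under_loops)) {
      if (nrow(l)) validate_intervals(loop_spans(l), genome)
    }
  }
  bins <- make_gene_bins(genes, genome)
  bins <- occupancy_bits(bins, peaks)
  nonempty <- bins$end > bins$start
  wt <- ko <- numeric(nrow(bins))
  wt[nonempty] <- track_mean(track_wt, bins[nonempty, , drop = FALSE])
  ko[nonempty] <- track_mean(track_ko, bins[nonempty, , drop = FALSE])
  bins$atac <- atac_diff(ko, wt, ko + wt, config$pseudocount_atac)
  wide_occ <- tidyr::pivot_wider(bins[c("gene_id", "bin", "occupied")],
                                 names_from = "bin", values_from = "occupied",
                                 names_prefix = "occ_")
  wide_atac <- tidyr::pivot_wider(bins[c("gene_id", "bin", "atac")],
                                  names_from = "bin", values_from = "atac",
                                  names_prefix = "atac_")
  out <- dplyr::left_join(wide_occ, wide_atac, by = "gene_id")
  out$satb1_loop_count <- anchor_gene_count(genes, satb1_loops)[match(out$gene_id, genes$gene_id)]
  out$ctcf_loop_count <- anchor_gene_count(genes, ctcf_loops)[match(out$gene_id, genes$gene_id)]
  out$satb1_enhancer_link_count <-
    enhancer_link_count(genes, satb1_loops, enhancers, config)[match(out$gene_id, genes$gene_id)]
  out$h3k27ac_over_count <- anchor_gene_count(genes, over_loops)[match(out$gene_id, genes$gene_id)]
  out$h3k27ac_under_count <- anchor_gene_count(genes, under_loops)[match(out$gene_id, genes$gene_id)]
  out <- dplyr::left_join(out, expression[c("gene_id", "log2fc")], by = "gene_id")
  miss <- is.na(out$log2fc)
  if (any(miss)) {
    message(sum(miss), " gene(s) without expression dropped from the model matrix")
    out <- out[!miss, , drop = FALSE]
  }
  out
}

#' Ordinary least-squares model of expression change
#'
#' Fits `log2fc` on every predictor column (all columns except `gene_id` and
#' `log2fc`) with an intercept, by OLS. A rank-deficient design is an error
#' naming the collinear columns.
#'
#' @param matrix Predictor tibble from [assemble_matrix()].
#' @return An object of class `expression_model`: list with `coefficients`
#'   (tibble: term, estimate, std_error, statistic, p_value), `r_squared`,
#'   `adj_r_squared`, `n`, and the underlying `fit`.
#' @export
fit_expression_model <- function(matrix) {
  pred <- setdiff(names(matrix), c("gene_id", "log2fc"))
  if (nrow(matrix) <= length(pred) + 1) stop("need more rows than columns")
  fml <- stats::reformulate(pred, response = "log2fc")
  fit <- stats::lm(fml, data = matrix)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  tss <- sum((matrix$log2fc - mean(matrix$log2fc))^2)
  r2 <- if (tss == 0) 0 else sm$r.squared
  adj <- if (tss == 0) 0 else sm$adj.r.squared
  structure(list(
    coefficients = tibble::tibble(term = rownames(co),
                                  estimate = unname(co[, 1]),
                                  std_error = unname(co[, 2]),
                                  statistic = unname(co[, 3]),
                                  p_value = unname(co[, 4])),
    r_squared = r2, adj_r_squared = adj, n = nrow(matrix), fit = fit),
    class = "expression_model")
}

#' @export
print.expression_model <- function(x, ...) {
  cat("Expression-change OLS model:", x$n, "genes, R-squared =",
      format(x$r_squared, digits = 4), "\n")
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}
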