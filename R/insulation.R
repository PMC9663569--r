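#' Length-normalised log expression score
#'
#' `log10(counts / gene_length + pseudocount)`: normalised counts are divided
#' by gene length so that genes of different sizes are comparable within a
#' sample, and a pseudocount keeps silent genes finite
#' (`counts = 0` gives `log10(pseudocount)`).
#'
#' @param counts Normalised count(s), >= 0.
#' @param gene_length Gene length(s) in bp, > 0.
#' @param pseudocount Pseudocount (default 0.01).
#' @return Numeric vector of scores.
#' @export
expression_score <- function(counts, gene_length, pseudocount = 0.01) {
  stopifnot(all(counts >= 0), all(gene_length > 0))
  log10(counts / gene_length + pseudocount)
}

#' @noRd
gene_scores <- function(genes, expression, config, condition = "wt") {
  counts <- expression[[paste0(condition, "_count")]]
  sc <- tibble::tibble(gene_id = expression$gene_id, count = counts)
  g <- dplyr::inner_join(genes, sc, by = "gene_id")
  g$score <- expression_score(g$count, g$end - g$start,
                              config$pseudocount_expression)
  g
}

# mean expression score of genes overlapping each window; windows carry loop_id
#' @noRd
window_gene_means <- function(windows, scored_genes) {
  hits <- overlap_pairs(windows, scored_genes)
  hits$loop_id <- windows$loop_id[hits$query]
  # a gene spanning two windows of the same loop is pooled once
  hits <- dplyr::distinct(hits, .data$loop_id, .data$subject)
  hits$score <- scored_genes$score[hits$subject]
  dplyr::summarise(dplyr::group_by(hits, .data$loop_id),
                   mean = mean(.data$score), n = dplyr::n(), .groups = "drop")
}

#' Transcriptional insulation scores of loops
#'
#' For each loop, the insulation score is the absolute difference between the
#' mean expression score of genes inside the loop span and the mean expression
#' score of genes in same-size regions immediately upstream and downstream of
#' the span (pooled into one flank mean). Genes are assigned to a region by
#' >= 1 bp overlap; flank windows are clipped at chromosome ends. Loops with
#' no inside or no flank genes are flagged invalid.
#'
#' @param loops Loop tibble.
#' @param genes Gene tibble.
#' @param expression Expression tibble (see [read_expression_table()]).
#' @param genome Optional genome tibble for clipping flank windows.
#' @param config A [run_config()].
#' @param condition Which normalised counts to score (`"wt"` or `"ko"`).
#' @return Tibble with one row per loop: `loop_id`, `inside_mean`,
#'   `flank_mean`, `score`, `n_inside`, `n_flank`, `valid`.
#' @export
insulation_score <- function(loops, genes, expression, genome = NULL,
                             config = run_config(), condition = "wt") {
  scored <- gene_scores(genes, expression, config, condition)
  spans <- loop_spans(loops)
  len <- spans$end - spans$start
  lim <- if (is.null(genome)) Inf else genome_size_of(genome, spans$chrom)
  flanks <- tibble::tibble(
    chrom = rep(spans$chrom, 2),
    start = c(pmax(spans$start - len, 0), pmin(spans$end, lim)),
    end = c(pmax(spans$start, 0), pmin(spans$end + len, lim)),
    loop_id = rep(spans$loop_id, 2))
  flanks <- flanks[flanks$end > flanks$start, , drop = FALSE]
  inside <- window_gene_means(spans, scored)
  flank <- window_gene_means(flanks, scored)
  out <- tibble::tibble(loop_id = spans$loop_id)
  out$inside_mean <- inside$mean[match(out$loop_id, inside$loop_id)]
  out$n_inside <- dplyr::coalesce(inside$n[match(out$loop_id, inside$loop_id)], 0L)
  out$flank_mean <- flank$mean[match(out$loop_id, flank$loop_id)]
  out$n_flank <- dplyr::coalesce(flank$n[match(out$loop_id, flank$loop_id)], 0L)
  out$score <- abs(out$inside_mean - out$flank_mean)
  out$valid <- out$n_inside > 0 & out$n_flank > 0
  out[c("loop_id", "inside_mean", "flank_mean", "score", "n_inside",
        "n_flank", "valid")]
}

#' Shuffled-loop null for the insulation score
#'
#' Repeats the insulation computation `n` times on loops randomly relocated
#' across the genome. Within each round, any relocated loop containing no gene
#' is re-drawn (up to `max_attempts` attempts, then dropped with a warning).
#' Pooled null scores are compared with the observed (valid) scores by a
#' two-sided Wilcoxon rank-sum test.
#'
#' @inheritParams insulation_score
#' @param genome Genome tibble (required: placement bounds).
#' @param seed Integer seed.
#' @param n Number of shuffle rounds.
#' @param max_attempts Re-draw cap per round for gene-less loops.
#' @return List with `observed` (tibble from [insulation_score()]),
#'   `null_scores` (numeric, pooled), `p_value`, and the two medians.
#' @export
insulation_null <- function(loops, genes, expression, genome, seed, n = 100,
                            config = run_config(), condition = "wt",
                            max_attempts = 1000) {
  stopifnot(n >= 1)
  observed <- insulation_score(loops, genes, expression, genome, config, condition)
  scored <- gene_scores(genes, expression, config, condition)
  gene_idx <- subject_index(scored)
  null_scores <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n), function(r) {
      shuf <- shuffle_loops_impl(loops, genome)
      for (attempt in seq_len(max_attempts)) {
        sp <- loop_spans(shuf)
        empty <- !overlaps_any_idx(sp$chrom, sp$start, sp$end, gene_idx)
        if (!any(empty)) break
        shuf[empty, ] <- shuffle_loops_impl(shuf[empty, , drop = FALSE], genome)
      }
      sp <- loop_spans(shuf)
      empty <- !overlaps_any_idx(sp$chrom, sp$start, sp$end, gene_idx)
      if (any(empty)) {
        warning(sum(empty), " shuffled loop(s) dropped after ", max_attempts,
                " gene-less re-draws")
        shuf <- shuf[!empty, , drop = FALSE]
      }
      if (nrow(shuf) == 0) {
        stop("genome too gene-poor to place shuffled loops")
      }
      res <- insulation_score(shuf, genes, expression, genome, config, condition)
      res$score[res$valid]
    }))
  })
  obs_scores <- observed$score[observed$valid]
  p <- if (length(obs_scores) && length(null_scores)) {
    suppressWarnings(stats::wilcox.test(obs_scores, null_scores,
                                        exact = FALSE)$p.value)
  } else NA_real_
  list(observed = observed, null_scores = null_scores, p_value = p,
       median_observed = stats::median(obs_scores),
       median_null = stats::median(null_scores))
}
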