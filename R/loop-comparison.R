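#' Overlap score of query loops against a reference loop set
#'
#' For every query loop, the score against one reference loop is
#' (number of overlapping bp) / (bp size of the query loop), where a loop's
#' size is its span length (outer coordinates of the two anchors). When a
#' query intersects several reference loops the maximum score is kept, so a
#' score of 1 means full containment (engulfment) of the query span in some
#' reference span and 0 means no overlap at all.
#'
#' @param query Loop tibble of query loops.
#' @param reference Loop tibble of reference loops (may be empty).
#' @return `query` with an added `overlap_score` column in `[0, 1]`.
#' @export
overlap_score <- function(query, reference) {
  qs <- loop_spans(query)
  score <- numeric(nrow(query))
  if (nrow(reference) > 0) {
    hits <- overlap_pairs(qs, loop_spans(reference))
    if (nrow(hits) > 0) {
      per <- hits$bp / (qs$end[hits$query] - qs$start[hits$query])
      best <- tapply(per, hits$query, max)
      score[as.integer(names(best))] <- as.numeric(best)
    }
  }
  out <- query
  out$overlap_score <- score
  out
}

#' Observed vs shuffled-loop overlap-score distributions
#'
#' Scores every query loop against the reference set, repeats the scoring for
#' the same loops randomly relocated across the genome (rigid spans), and
#' compares the two score distributions with a two-sided Wilcoxon rank-sum
#' test.
#'
#' @param query,reference Loop tibbles.
#' @param genome Genome tibble.
#' @param seed Integer seed for the shuffle.
#' @param same_chrom Restrict the shuffle to each loop's own chromosome?
#' @return A list with `scores` (tibble: `loop_id`, `set` in
#'   observed/shuffled, `overlap_score`), `p_value`, and the two medians.
#' @export
score_distribution <- function(query, reference, genome, seed,
                               same_chrom = FALSE) {
  obs <- overlap_score(query, reference)$overlap_score
  shuf <- overlap_score(shuffle_loops(query, genome, seed, same_chrom),
                        reference)$overlap_score
  scores <- tibble::tibble(
    loop_id = rep(query$loop_id, 2),
    set = rep(c("observed", "shuffled"), each = nrow(query)),
    overlap_score = c(obs, shuf))
  p <- if (nrow(query) > 0) {
    suppressWarnings(stats::wilcox.test(obs, shuf, exact = FALSE)$p.value)
  } else NA_real_
  list(scores = scores, p_value = p,
       median_observed = stats::median(obs), median_shuffled = stats::median(shuf))
}

#' Fraction of loops in A whose span overlaps any loop span in B
#'
#' @param loops_a,loops_b Loop tibbles.
#' @return A fraction in `[0, 1]`.
#' @export
fraction_overlapping <- function(loops_a, loops_b) {
  if (nrow(loops_a) == 0) return(NA_real_)
  mean(overlaps_any(loop_spans(loops_a), loop_spans(loops_b)))
}

#' Merge all loop anchors into unique regions
#'
#' Extracts the anchors from both sides of every loop and merges them into
#' non-overlapping unique regions.
#'
#' @param loops Loop tibble.
#' @return Sorted, disjoint interval tibble.
#' @export
merge_loop_anchors <- function(loops) {
  merge_intervals(loop_anchors(loops))
}

#' Promoter windows of genes
#'
#' The promoter of a gene is its TSS extended by `promoter_extension` bp in
#' the direction of transcription (downstream into the gene body on the coding
#' strand), clipped to the gene's chromosome when a genome is given.
#'
#' @param genes Gene tibble (`chrom, start, end, strand, gene_id`).
#' @param config A [run_config()].
#' @param genome Optional genome tibble used to clip windows.
#' @return Interval tibble of promoter windows keyed by `gene_id`.
#' @export
promoter_windows <- function(genes, config = run_config(), genome = NULL) {
  ext <- config$promoter_extension
  plus <- genes$strand != "-"
  tss <- ifelse(plus, genes$start, genes$end - 1)
  start <- ifelse(plus, tss, tss - ext + 1)
  end <- ifelse(plus, tss + ext, tss + 1)
  start <- pmax(start, 0)
  if (!is.null(genome)) end <- pmin(end, genome_size_of(genome, genes$chrom))
  tibble::tibble(chrom = genes$chrom, start = start, end = end,
                 strand = genes$strand, gene_id = genes$gene_id)
}

#' Enhancer test windows (center +/- flank)
#'
#' @param enhancers Interval tibble of enhancer records.
#' @param config A [run_config()]; `enhancer_flank` sets the half-width.
#' @return Interval tibble of windows centered on each enhancer.
#' @export
enhancer_windows <- function(enhancers, config = run_config()) {
  center <- floor((enhancers$start + enhancers$end) / 2)
  tibble::tibble(chrom = enhancers$chrom,
                 start = pmax(center - config$enhancer_flank, 0),
                 end = center + config$enhancer_flank,
                 strand = "*")
}

#' Classify loops by promoter/enhancer content of their anchors
#'
#' Each anchor is flagged for >= 1 bp overlap with a promoter window
#' (TSS extended by `promoter_extension`) and with an enhancer window
#' (center +/- `enhancer_flank`); the loop category is derived from the four
#' flags: promoter-enhancer (one anchor with a promoter, the other with an
#' enhancer), promoter-promoter, enhancer-enhancer, promoter-only,
#' enhancer-only, neither.
#'
#' @param loops Loop tibble.
#' @param enhancers Enhancer interval tibble (raw records; windows are derived).
#' @param genes Gene tibble.
#' @param config A [run_config()].
#' @param genome Optional genome for clipping promoter windows.
#' @return `loops` with flag columns and a `category` column.
#' @export
classify_loops <- function(loops, enhancers, genes, config = run_config(),
                           genome = NULL) {
  prom <- promoter_windows(genes, config, genome)
  enh <- enhancer_windows(enhancers, config)
  anch <- loop_anchors(loops)
  hit_p <- overlaps_any(anch, prom)
  hit_e <- overlaps_any(anch, enh)
  # loop_anchors() stacks all left anchors (in row order) then all right ones
  left <- anch$side == "left"
  out <- loops
  out$has_promoter_left <- hit_p[left]
  out$has_promoter_right <- hit_p[!left]
  out$has_enhancer_left <- hit_e[left]
  out$has_enhancer_right <- hit_e[!left]
  out$category <- loop_category(out$has_promoter_left, out$has_promoter_right,
                                out$has_enhancer_left, out$has_enhancer_right)
  out
}

#' @noRd
loop_category <- function(pl, pr, el, er) {
  pe <- (pl & er) | (pr & el)
  pp <- pl & pr
  ee <- el & er
  anyp <- pl | pr
  anye <- el | er
  dplyr::case_when(
    pe ~ "promoter-enhancer",
    pp ~ "promoter-promoter",
    ee ~ "enhancer-enhancer",
    anyp ~ "promoter-only",
    anye ~ "enhancer-only",
    TRUE ~ "neither")
}

#' Category odds ratio between two loop sets
#'
#' Odds ratio per the convention (factor2 in-category proportion) /
#' (factor1 in-category proportion), with a two-sided Fisher exact p from the
#' 2x2 table of in-category vs not for the two factors.
#'
#' @param f1_in_cat,f1_total Counts for factor 1 (denominator of the ratio).
#' @param f2_in_cat,f2_total Counts for factor 2.
#' @return One-row tibble with `ratio`, `fisher_p` and an `infinite` flag
#'   (`TRUE` when factor 1 has no loops in the category).
#' @export
category_odds_ratio <- function(f1_in_cat, f1_total, f2_in_cat, f2_total) {
  stopifnot(f1_total > 0, f2_total > 0)
  infinite <- f1_in_cat == 0
  ratio <- if (infinite) Inf else (f2_in_cat / f2_total) / (f1_in_cat / f1_total)
  tab <- matrix(c(f2_in_cat, f2_total - f2_in_cat,
                  f1_in_cat, f1_total - f1_in_cat), nrow = 2)
  p <- stats::fisher.test(tab)$p.value
  tibble::tibble(ratio = ratio, fisher_p = p, infinite = infinite)
}

#' Per-category odds-ratio summary for two classified loop sets
#'
#' Runs [category_odds_ratio()] for every category present in either set and
#' adds Benjamini-Hochberg adjusted Fisher p-values.
#'
#' @param loops1,loops2 Outputs of [classify_loops()] (factor 1 and factor 2).
#' @return Tibble with one row per category.
#' @export
category_table <- function(loops1, loops2) {
  cats <- sort(unique(c(loops1$category, loops2$category)))
  out <- purrr::map_dfr(cats, function(cat) {
    r <- category_odds_ratio(sum(loops1$category == cat), nrow(loops1),
                             sum(loops2$category == cat), nrow(loops2))
    dplyr::bind_cols(tibble::tibble(category = cat,
                                    n_factor1 = sum(loops1$category == cat),
                                    n_factor2 = sum(loops2$category == cat)), r)
  })
  out$fisher_p_adj <- stats::p.adjust(out$fisher_p, method = "BH")
  out
}
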