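#' Permutation test for overlap between two interval sets
#'
#' The observed statistic is the number of intervals in `set_a` overlapping
#' (>= 1 bp) at least one interval of `set_b`. `set_a` is randomly relocated
#' across the genome `n_perm` times and the statistic recomputed; the p-value
#' follows the counting rule p = (number of rounds where the permuted overlap
#' exceeds the observed one) / `n_perm`. Enrichment is observed / mean null.
#' `conservative = TRUE` switches to the (k+1)/(n+1) correction instead.
#'
#' @param set_a,set_b Interval tibbles.
#' @param genome Genome tibble.
#' @param seed Integer seed.
#' @param n_perm Number of permutation rounds (default 1000).
#' @param conservative Use the (k+1)/(n+1) p-value instead of the plain k/n?
#' @param same_chrom Restrict the shuffle to each interval's chromosome?
#' @return One-row tibble: `observed`, `mean_null`, `enrichment`, `p_value`,
#'   `n_permutations`, and the null counts as a list-column `null_counts`.
#' @export
permutation_overlap_test <- function(set_a, set_b, genome, seed,
                                     n_perm = 1000, conservative = FALSE,
                                     same_chrom = FALSE) {
  stopifnot(n_perm >= 1, nrow(set_a) > 0)
  idx <- subject_index(set_b)
  observed <- sum(overlaps_any_idx(set_a$chrom, set_a$start, set_a$end, idx))
  k <- nrow(set_a)
  len <- set_a$end - set_a$start
  null_counts <- withr::with_seed(seed, {
    m <- n_perm * k
    lens <- rep(len, times = n_perm)
    if (same_chrom) {
      size <- rep(genome_size_of(genome, set_a$chrom), times = n_perm)
      if (any(lens > size)) stop("interval longer than its chromosome")
      cap <- size - lens + 1
      chroms <- rep(set_a$chrom, times = n_perm)
    } else {
      cap_mat <- outer(len, genome$size, function(l, s) pmax(0, s - l + 1))
      tot <- rowSums(cap_mat)
      if (any(tot == 0)) stop("interval longer than every chromosome")
      cum <- row_cumsum(cap_mat)
      cum_rep <- cum[rep(seq_len(k), times = n_perm), , drop = FALSE]
      u <- stats::runif(m) * rep(tot, times = n_perm)
      ci <- rowSums(cum_rep < u) + 1
      chroms <- genome$chrom[ci]
      cap <- cap_mat[cbind(rep(seq_len(k), times = n_perm), ci)]
    }
    starts <- pmin(floor(stats::runif(m) * cap), cap - 1)
    hits <- overlaps_any_idx(chroms, starts, starts + lens, idx)
    as.numeric(rowsum(as.numeric(hits), rep(seq_len(n_perm), each = k)))
  })
  exceed <- sum(null_counts > observed)
  p <- if (conservative) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  tibble::tibble(observed = observed, mean_null = mean(null_counts),
                 enrichment = observed / mean(null_counts), p_value = p,
                 n_permutations = n_perm, null_counts = list(null_counts))
}

#' Binding-site scoring windows (center +/- flank, center base included)
#'
#' Each site is reduced to its central base and extended `peak_flank` bp both
#' ways, giving windows of `2 * peak_flank + 1` bp.
#'
#' @param peaks Interval tibble of binding sites.
#' @param config A [run_config()].
#' @return Interval tibble of scoring windows.
#' @export
peak_windows <- function(peaks, config = run_config()) {
  center <- floor((peaks$start + peaks$end) / 2)
  tibble::tibble(chrom = peaks$chrom,
                 start = pmax(center - config$peak_flank, 0),
                 end = center + config$peak_flank + 1,
                 strand = "*")
}

#' @noRd
peak_scores <- function(windows, track, config) {
  log10(pmax(track_mean(track, windows), config$pseudocount_atac))
}

#' Bootstrap test of accessibility at binding sites
#'
#' Each binding site is scored as log10 of the mean track signal over its
#' center +/- `peak_flank` window (a zero mean is floored at
#' `pseudocount_atac` before the log). The real statistic is the mean of the
#' per-site scores. Windows are then randomly relocated across the genome `n`
#' times; the bootstrap p-value is (number of permuted mean values bigger than
#' the real mean) / `n`.
#'
#' @param peaks Interval tibble of binding sites (non-empty).
#' @param track Signal track tibble (non-empty).
#' @param genome Genome tibble.
#' @param seed Integer seed.
#' @param n Number of permutation rounds (default 100).
#' @param config A [run_config()].
#' @return List with `real_mean`, `null_means` (length `n`), `p_value` and the
#'   per-site `scores`.
#' @export
peak_accessibility_test <- function(peaks, track, genome, seed, n = 100,
                                    config = run_config()) {
  if (nrow(peaks) == 0) stop("`peaks` must be non-empty")
  if (nrow(track) == 0) stop("`track` is empty")
  windows <- peak_windows(peaks, config)
  scores <- peak_scores(windows, track, config)
  real_mean <- mean(scores)
  null_means <- withr::with_seed(seed, {
    vapply(seq_len(n), function(r) {
      shuf <- shuffle_intervals_impl(windows, genome)
      mean(peak_scores(shuf, track, config))
    }, numeric(1))
  })
  list(real_mean = real_mean, null_means = null_means,
       p_value = sum(null_means > real_mean) / n, scores = scores)
}

#' Binding sites with low accessibility
#'
#' Scores sites as in [peak_accessibility_test()], runs `n` shuffling rounds,
#' and uses the average of the per-round mean null scores as a cutoff: sites
#' scoring below the cutoff are returned as the low-accessibility subset.
#'
#' @inheritParams peak_accessibility_test
#' @param n Number of shuffling rounds used for the cutoff (default 10).
#' @return List with `peaks` (subset tibble with a `score` column), `cutoff`,
#'   and all per-site `scores`.
#' @export
low_accessibility_subset <- function(peaks, track, genome, seed, n = 10,
                                     config = run_config()) {
  test <- peak_accessibility_test(peaks, track, genome, seed, n, config)
  cutoff <- mean(test$null_means)
  out <- peaks
  out$score <- test$scores
  list(peaks = out[out$score < cutoff, , drop = FALSE], cutoff = cutoff,
       scores = test$scores)
}
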