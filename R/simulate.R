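#' Configuration for the synthetic-data generator
#'
#' The generator emits a complete input bundle — genome, non-overlapping
#' stranded genes, a large-span structural loop set (factor B, CTCF-like), a
#' smaller-span loop set nested inside it with a controllable engulfment
#' fraction (factor A, SATB1-like), enhancers (a fraction tethered to factor-A
#' right anchors), binding sites with elevated accessibility, wild-type and
#' knockout signal tracks, negative-binomial expression counts with planted
#' effects, and differential (over-/under-interacting) loops whose per-gene
#' linking score is coupled to expression change through a Gaussian copula on
#' ranks — so that every downstream statistic has ground truth.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @param n_chromosomes,chrom_length Genome shape (default 4 x 200 Mbp,
#'   chosen so that the default factor-B loop set covers roughly 40% of the
#'   genome, the coverage the scaled-down loop counts imply).
#' @param n_genes Number of genes (default 2000).
#' @param gene_meanlog,gene_sdlog Log-normal gene-length parameters.
#' @param n_factor_a_loops,n_factor_b_loops Loop counts (default 500 / 800).
#' @param a_span_meanlog,a_span_sdlog,b_span_meanlog,b_span_sdlog Log-normal
#'   span-length parameters for the two factors (factor B spans larger).
#' @param anchor_width Anchor width in bp (default 5000, the loop-calling
#'   resolution).
#' @param engulfment_fraction Probability that a factor-A span is placed fully
#'   inside a factor-B span (default 0.9).
#' @param n_enhancers,enhancer_width Enhancer records (default 800 x 1000 bp).
#' @param fraction_loops_to_enhancer Fraction of factor-A loops whose right
#'   anchor carries an enhancer (default 0.3).
#' @param n_peaks,peak_width Binding sites (default 2000 x 600 bp).
#' @param peak_signal_ratio Accessibility at sites vs background (default 10).
#' @param ko_accessibility_drop Fractional signal loss at sites in the
#'   knockout (default 0.5).
#' @param planted_log2fc_in_a_loops Mean expression log2FC planted on genes
#'   overlapping factor-A anchors (default -1: repression in the knockout).
#' @param lfc_noise_sd Gene-level sd around the planted log2FC (default 0.3).
#' @param expression_meanlog,expression_sdlog Baseline count distribution.
#' @param dispersion Negative-binomial dispersion (variance = mu + mu^2 /
#'   dispersion; default 10).
#' @param insulation_shift Baseline expression of genes inside factor-A spans
#'   is multiplied by `10^insulation_shift` (default 1), planting an
#'   inside-vs-flank expression-score difference.
#' @param linking_correlation Target Spearman correlation between the
#'   per-gene linking score and expression log2FC (default 0.6).
#' @param linking_score_sd Spread of planted integer linking scores
#'   (default 3).
#' @param n_balanced_pairs Genes receiving one over- plus one under-
#'   interacting loop (score-neutral background; default 200).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_chromosomes = 4L, chrom_length = 200e6,
                       n_genes = 2000L,
                       gene_meanlog = log(8000), gene_sdlog = 0.6,
                       n_factor_a_loops = 500L, n_factor_b_loops = 800L,
                       a_span_meanlog = log(1e5), a_span_sdlog = 0.35,
                       b_span_meanlog = log(4e5), b_span_sdlog = 0.35,
                       anchor_width = 5000,
                       engulfment_fraction = 0.9,
                       n_enhancers = 800L, enhancer_width = 1000,
                       fraction_loops_to_enhancer = 0.3,
                       n_peaks = 2000L, peak_width = 600,
                       peak_signal_ratio = 10,
                       ko_accessibility_drop = 0.5,
                       planted_log2fc_in_a_loops = -1,
                       lfc_noise_sd = 0.3,
                       expression_meanlog = log(500), expression_sdlog = 1,
                       dispersion = 10,
                       insulation_shift = 1,
                       linking_correlation = 0.6,
                       linking_score_sd = 3,
                       n_balanced_pairs = 200L) {
  cfg <- as.list(environment())
  fracs <- c("engulfment_fraction", "fraction_loops_to_enhancer")
  if (any(unlist(cfg[fracs]) < 0 | unlist(cfg[fracs]) > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  if (abs(linking_correlation) > 1) stop("linking_correlation must be in [-1, 1]")
  counts <- c("n_chromosomes", "n_genes", "n_factor_a_loops", "n_factor_b_loops",
              "n_enhancers", "n_peaks")
  if (any(unlist(cfg[counts]) <= 0)) stop("counts must be positive")
  if (dispersion <= 0) stop("dispersion must be positive")
  structure(cfg, class = "sim_config")
}

#' Negative-binomial count draws
#'
#' Standard NB parameterisation: variance = mean + mean^2 / dispersion.
#'
#' @param n Number of draws.
#' @param mean Mean(s), >= 0.
#' @param dispersion Dispersion (size) parameter, > 0.
#' @param seed Optional seed for a reproducible draw.
#' @return Integer-valued numeric vector.
#' @export
generate_counts <- function(n, mean, dispersion, seed = NULL) {
  stopifnot(all(mean >= 0), dispersion > 0)
  draw <- function() stats::rnbinom(n, mu = mean, size = dispersion)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# greedily place non-overlapping intervals (gap-separated), drawing in batches
#' @noRd
place_disjoint <- function(n, lengths_fn, genome, gap = 2000, max_rounds = 40) {
  kept <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  for (round in seq_len(max_rounds)) {
    need <- n - nrow(kept)
    if (need <= 0) break
    m <- max(2 * need, 50)
    len <- lengths_fn(m)
    cand <- shuffle_intervals_impl(
      tibble::tibble(chrom = genome$chrom[1], start = 0, end = len), genome)
    pool <- dplyr::arrange(dplyr::bind_rows(kept, cand), .data$chrom, .data$start)
    keep <- logical(nrow(pool))
    prev_chrom <- ""; prev_end <- -Inf
    for (i in seq_len(nrow(pool))) {
      if (pool$chrom[i] != prev_chrom || pool$start[i] >= prev_end + gap) {
        keep[i] <- TRUE
        prev_chrom <- pool$chrom[i]; prev_end <- pool$end[i]
      }
    }
    kept <- pool[keep, , drop = FALSE]
    if (nrow(kept) >= n) {
      kept <- kept[sample.int(nrow(kept), n), , drop = FALSE]
      kept <- dplyr::arrange(kept, .data$chrom, .data$start)
      break
    }
  }
  if (nrow(kept) < n) stop("could not place ", n, " disjoint intervals")
  kept
}

#' Generate a complete synthetic input bundle
#'
#' See [sim_config()] for the generative model. All randomness is governed by
#' `config$seed`; the same configuration always regenerates an identical
#' bundle.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome`, `genes`, `loops_a`, `loops_b`,
#'   `loops_over`, `loops_under`, `enhancers`, `peaks`, `track_wt`,
#'   `track_ko`, `expression`, `truth` and the `config` itself.
#' @export
simulate_bundle <- function(config = sim_config()) {
  withr::with_seed(config$seed, simulate_bundle_impl(config))
}

#' @noRd
simulate_bundle_impl <- function(cfg) {
  genome <- as_genome(stats::setNames(rep(cfg$chrom_length, cfg$n_chromosomes),
                                      paste0("chr", seq_len(cfg$n_chromosomes))))
  max_len <- max(genome$size)

  # --- genes: disjoint, stranded, log-normal lengths
  gene_len_fn <- function(m) pmin(pmax(round(stats::rlnorm(
    m, cfg$gene_meanlog, cfg$gene_sdlog)), 200), 100000)
  genes <- place_disjoint(cfg$n_genes, gene_len_fn, genome)
  genes$strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  genes$gene_id <- sprintf("gene_%04d", seq_len(cfg$n_genes))

  # --- factor-B loops (large spans), uniform placement
  b_span <- pmin(pmax(round(stats::rlnorm(
    cfg$n_factor_b_loops, cfg$b_span_meanlog, cfg$b_span_sdlog)), 50000),
    min(2e6, max_len))
  b_spans <- shuffle_intervals_impl(
    tibble::tibble(chrom = genome$chrom[1], start = 0, end = b_span), genome)
  loops_b <- gloops(b_spans$chrom, b_spans$start,
                    b_spans$start + cfg$anchor_width,
                    b_spans$end - cfg$anchor_width, b_spans$end)

  # --- factor-A loops: engulfed in a random factor-B span w.p.
  #     engulfment_fraction, else uniform
  a_span <- pmin(pmax(round(stats::rlnorm(
    cfg$n_factor_a_loops, cfg$a_span_meanlog, cfg$a_span_sdlog)),
    2 * cfg$anchor_width + 1000), max_len)
  engulf <- stats::runif(cfg$n_factor_a_loops) < cfg$engulfment_fraction
  a_chrom <- character(cfg$n_factor_a_loops)
  a_start <- numeric(cfg$n_factor_a_loops)
  b_len <- b_spans$end - b_spans$start
  for (i in seq_len(cfg$n_factor_a_loops)) {
    host <- which(b_len > a_span[i])
    if (engulf[i] && length(host)) {
      h <- host[sample.int(length(host), 1)]
      a_chrom[i] <- b_spans$chrom[h]
      a_start[i] <- b_spans$start[h] +
        floor(stats::runif(1) * (b_len[h] - a_span[i] + 1))
    } else {
      pl <- shuffle_intervals_impl(
        tibble::tibble(chrom = genome$chrom[1], start = 0, end = a_span[i]),
        genome)
      a_chrom[i] <- pl$chrom; a_start[i] <- pl$start
    }
  }
  loops_a <- gloops(a_chrom, a_start, a_start + cfg$anchor_width,
                    a_start + a_span - cfg$anchor_width, a_start + a_span)
  truth_engulfed <- engulf

  # --- enhancers: a fraction sit in factor-A right anchors, rest random
  n_linked <- round(cfg$fraction_loops_to_enhancer * cfg$n_factor_a_loops)
  linked_idx <- sample.int(cfg$n_factor_a_loops, n_linked)
  linked_center <- floor((loops_a$start2[linked_idx] + loops_a$end2[linked_idx]) / 2)
  linked_enh <- tibble::tibble(
    chrom = loops_a$chrom[linked_idx],
    start = pmax(linked_center - cfg$enhancer_width / 2, 0),
    end = linked_center + cfg$enhancer_width / 2)
  n_rand <- max(cfg$n_enhancers - n_linked, 0)
  rand_enh <- shuffle_intervals_impl(
    tibble::tibble(chrom = genome$chrom[1], start = 0,
                   end = rep(cfg$enhancer_width, n_rand)), genome)
  enhancers <- dplyr::arrange(
    dplyr::bind_rows(linked_enh, rand_enh[c("chrom", "start", "end")]),
    .data$chrom, .data$start)
  enhancers$strand <- "*"

  # --- binding sites and accessibility tracks
  peaks <- place_disjoint(cfg$n_peaks, function(m) rep(cfg$peak_width, m),
                          genome, gap = 2000)
  peaks$strand <- "*"
  windows <- merge_intervals(tibble::tibble(
    chrom = peaks$chrom,
    start = pmax(floor((peaks$start + peaks$end) / 2) - 250, 0),
    end = floor((peaks$start + peaks$end) / 2) + 251))
  track_wt <- flat_track_with_islands(genome, windows, background = 1,
                                      island = cfg$peak_signal_ratio)
  track_ko <- flat_track_with_islands(
    genome, windows, background = 1,
    island = cfg$peak_signal_ratio * (1 - cfg$ko_accessibility_drop))

  # --- expression with planted effects
  in_a_span <- overlaps_any(genes, loop_spans(loops_a))
  in_a_anchor <- anchor_gene_count(genes, loops_a) > 0
  mu <- stats::rlnorm(cfg$n_genes, cfg$expression_meanlog, cfg$expression_sdlog)
  mu <- mu * ifelse(in_a_span, 10^cfg$insulation_shift, 1)
  lfc_true <- stats::rnorm(cfg$n_genes, 0, cfg$lfc_noise_sd) +
    ifelse(in_a_anchor, cfg$planted_log2fc_in_a_loops, 0)
  wt_count <- stats::rnbinom(cfg$n_genes, mu = mu, size = cfg$dispersion)
  ko_count <- stats::rnbinom(cfg$n_genes, mu = mu * 2^lfc_true,
                             size = cfg$dispersion)
  log2fc <- log2((ko_count + 0.5) / (wt_count + 0.5))
  pval <- 2 * pmin(stats::pnbinom(ko_count, mu = pmax(mu, 1e-8),
                                  size = cfg$dispersion),
                   stats::pnbinom(ko_count - 1, mu = pmax(mu, 1e-8),
                                  size = cfg$dispersion, lower.tail = FALSE))
  expression <- tibble::tibble(gene_id = genes$gene_id,
                               wt_count = as.numeric(wt_count),
                               ko_count = as.numeric(ko_count),
                               log2fc = log2fc,
                               fdr = stats::p.adjust(pmin(pval, 1), "BH"))

  # --- differential loops coupled to expression via a Gaussian copula
  n <- cfg$n_genes
  z1 <- stats::qnorm((rank(log2fc, ties.method = "average") - 0.5) / n)
  r_latent <- 2 * sin(pi * cfg$linking_correlation / 6)
  z2 <- r_latent * z1 + sqrt(1 - r_latent^2) * stats::rnorm(n)
  score_true <- as.integer(round(z2 * cfg$linking_score_sd))
  diff_loops <- plant_differential_loops(genes, score_true, genome, cfg)
  balanced <- sample.int(n, min(cfg$n_balanced_pairs, n))
  bal_over <- plant_differential_loops(genes[balanced, ],
                                       rep(1L, length(balanced)), genome, cfg,
                                       avoid_genes = genes)
  bal_under <- plant_differential_loops(genes[balanced, ],
                                        rep(-1L, length(balanced)), genome, cfg,
                                        avoid_genes = genes)
  over <- dplyr::bind_rows(diff_loops$over, bal_over$over)
  under <- dplyr::bind_rows(diff_loops$under, bal_under$under)
  loops_over <- gloops(over$chrom, over$start1, over$end1, over$start2,
                       over$end2, label = "overinteracting")
  loops_under <- gloops(under$chrom, under$start1, under$end1, under$start2,
                        under$end2, label = "underinteracting")

  truth <- tibble::tibble(gene_id = genes$gene_id,
                          in_a_span = in_a_span,
                          in_a_anchor = in_a_anchor,
                          mu_baseline = mu,
                          lfc_true = lfc_true,
                          linking_score_true = score_true)

  list(genome = genome, genes = genes[c("chrom", "start", "end", "strand",
                                        "gene_id")],
       loops_a = loops_a, loops_b = loops_b,
       loops_over = loops_over, loops_under = loops_under,
       enhancers = enhancers, peaks = peaks[c("chrom", "start", "end", "strand")],
       track_wt = track_wt, track_ko = track_ko,
       expression = expression, truth = truth,
       engulfed = truth_engulfed, config = cfg)
}

# piecewise-constant track: `background` everywhere, `island` on the given
# disjoint windows; run-length encoded (one record per constant stretch)
#' @noRd
flat_track_with_islands <- function(genome, windows, background, island) {
  recs <- purrr::map_dfr(seq_len(nrow(genome)), function(ci) {
    size <- genome$size[ci]
    w <- windows[windows$chrom == genome$chrom[ci], , drop = FALSE]
    w$end <- pmin(w$end, size)
    edges <- sort(unique(c(0, w$start, w$end, size)))
    starts <- edges[-length(edges)]; ends <- edges[-1]
    inside <- vapply(starts, function(s) any(w$start <= s & w$end > s),
                     logical(1))
    tibble::tibble(chrom = genome$chrom[ci], start = starts, end = ends,
                   value = ifelse(inside, island, background))
  })
  as_track(recs)
}

# one loop per |score| unit: left anchor inside the gene, right anchor at a
# random offset avoiding other genes (so counts stay attributable)
#' @noRd
plant_differential_loops <- function(genes, score, genome, cfg,
                                     avoid_genes = genes) {
  gene_idx <- subject_index(avoid_genes)
  sizes <- genome_size_of(genome, genes$chrom)
  one_set <- function(sel) {
    if (!length(sel)) {
      return(tibble::tibble(chrom = character(), start1 = numeric(),
                            end1 = numeric(), start2 = numeric(),
                            end2 = numeric()))
    }
    reps <- abs(score[sel])
    gi <- rep(sel, reps)
    aw <- cfg$anchor_width
    left_start <- genes$start[gi]
    left_end <- pmin(genes$end[gi], genes$start[gi] + aw)
    right_start <- numeric(length(gi))
    for (j in seq_along(gi)) {
      size <- sizes[gi[j]]
      for (try in 1:50) {
        off <- floor(stats::runif(1, 5e4, 5e5))
        cand <- if (genes$end[gi[j]] + off + aw <= size) {
          genes$end[gi[j]] + off
        } else {
          max(genes$start[gi[j]] - off - aw, 0)
        }
        if (!overlaps_any_idx(genes$chrom[gi[j]], cand, cand + aw, gene_idx)) break
      }
      right_start[j] <- cand
    }
    tibble::tibble(chrom = genes$chrom[gi], start1 = left_start,
                   end1 = left_end, start2 = right_start,
                   end2 = right_start + aw)
  }
  list(over = one_set(which(score > 0)), under = one_set(which(score < 0)))
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard plain-text formats: `chrom.sizes`, `genes.bed`,
#' `enhancers.bed`, `peaks.bed`, four BEDPE loop files, two bedGraph tracks,
#' `expression.tsv` and `truth.tsv`. Output is deterministic for a given
#' bundle (the same bundle always writes byte-identical files).
#'
#' @param bundle Output of [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  utils::write.table(data.frame(bundle$genome$chrom,
                                format_coord(bundle$genome$size)),
                     p("chrom.sizes"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_bed(bundle$genes, p("genes.bed"))
  write_bed(bundle$enhancers, p("enhancers.bed"))
  write_bed(bundle$peaks, p("peaks.bed"))
  write_bedpe(bundle$loops_a, p("loops_factorA.bedpe"))
  write_bedpe(bundle$loops_b, p("loops_factorB.bedpe"))
  write_bedpe(bundle$loops_over, p("loops_overinteracting.bedpe"))
  write_bedpe(bundle$loops_under, p("loops_underinteracting.bedpe"))
  write_bedgraph(bundle$track_wt, p("atac_wt.bedgraph"))
  write_bedgraph(bundle$track_ko, p("atac_ko.bedgraph"))
  tsv <- function(x, f) {
    df <- as.data.frame(x)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) format(v, digits = 12, trim = TRUE,
                                                  scientific = FALSE))
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(bundle$expression, "expression.tsv")
  tsv(bundle$truth, "truth.tsv")
  invisible(dir)
}
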