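query_loop <- function() gloops("chr1", 100e3, 105e3, 200e3, 205e3)

test_that("overlap score is 1 under engulfment, 0 without shared bases", {
  ref <- gloops("chr1", 50e3, 55e3, 295e3, 300e3)
  expect_equal(overlap_score(query_loop(), ref)$overlap_score, 1.0)
  other_chrom <- gloops("chr2", 50e3, 55e3, 295e3, 300e3)
  expect_equal(overlap_score(query_loop(), other_chrom)$overlap_score, 0.0)
  empty <- gloops(character(), numeric(), numeric(), numeric(), numeric())
  expect_equal(overlap_score(query_loop(), empty)$overlap_score, 0.0)
})

test_that("overlap score takes the maximum across reference loops and matches the per-bp oracle", {
  q <- gloops("chr1", 1000, 1200, 1800, 2000) # span [1000, 2000)
  ref <- gloops(c("chr1", "chr1"), c(1500, 1900), c(1600, 1950),
                c(2900, 2050), c(3000, 2100))
  expect_equal(overlap_score(q, ref)$overlap_score, 0.5)
  set.seed(8)
  g <- small_genome()
  for (i in 1:15) {
    spans_q <- rand_intervals(4, g, sample(2000:20000, 4, replace = TRUE))
    spans_r <- rand_intervals(6, g, sample(2000:50000, 6, replace = TRUE))
    ql <- gloops(spans_q$chrom, spans_q$start, spans_q$start + 500,
                 spans_q$end - 500, spans_q$end)
    rl <- gloops(spans_r$chrom, spans_r$start, spans_r$start + 500,
                 spans_r$end - 500, spans_r$end)
    got <- overlap_score(ql, rl)$overlap_score
    want <- vapply(seq_len(4), function(j) {
      oracle_overlap_score(spans_q$start[j], spans_q$end[j],
                           spans_r[spans_r$chrom == spans_q$chrom[j], ])
    }, numeric(1))
    expect_equal(got, want)
  }
})

test_that("overlap score is 1 against itself and monotone in the reference set", {
  set.seed(15)
  g <- small_genome()
  spans <- rand_intervals(10, g, sample(5000:50000, 10, replace = TRUE))
  loops <- gloops(spans$chrom, spans$start, spans$start + 1000,
                  spans$end - 1000, spans$end)
  expect_equal(overlap_score(loops, loops)$overlap_score, rep(1, 10))
  sub <- loops[1:4, ]
  s_small <- overlap_score(loops, sub)$overlap_score
  s_big <- overlap_score(loops, loops)$overlap_score
  expect_true(all(s_big >= s_small))
})

test_that("score_distribution separates engulfed loops from shuffled controls", {
  # factor-B spans cover ~30% of the genome, as in the scaled study conditions
  b <- simulate_bundle(sim_config(n_chromosomes = 2, chrom_length = 100e6,
                                  n_genes = 200, n_factor_a_loops = 120,
                                  n_factor_b_loops = 150, n_peaks = 50,
                                  n_balanced_pairs = 20,
                                  engulfment_fraction = 0.9))
  d <- score_distribution(b$loops_a, b$loops_b, b$genome, seed = 31)
  expect_gt(d$median_observed, d$median_shuffled)
  expect_lt(d$p_value, 0.01)
  self <- score_distribution(b$loops_b, b$loops_b, b$genome, seed = 1)
  expect_true(all(self$scores$overlap_score[self$scores$set == "observed"] == 1))
})

test_that("fraction_overlapping counts span hits", {
  a <- gloops(rep("chr1", 4), c(0, 100e3, 200e3, 300e3),
              c(0, 100e3, 200e3, 300e3) + 5e3,
              c(50e3, 150e3, 250e3, 350e3),
              c(50e3, 150e3, 250e3, 350e3) + 5e3)
  b <- gloops("chr1", 0, 5e3, 250e3, 255e3) # span [0, 255e3) hits first 3
  expect_equal(fraction_overlapping(a, b), 0.75)
  expect_equal(fraction_overlapping(a, a), 1)
  other <- gloops("chr2", 0, 5e3, 250e3, 255e3)
  expect_equal(fraction_overlapping(a, other), 0)
})

test_that("merge_loop_anchors yields the disjoint union of all anchors", {
  l <- gloops(c("chr1", "chr1"), c(0, 4000), c(5000, 9000),
              c(10000, 20000), c(15000, 25000))
  m <- merge_loop_anchors(l)
  expect_equal(m$start, c(0, 10000, 20000))
  expect_equal(m$end, c(9000, 15000, 25000))
  # shared anchor appears once
  shared <- gloops(c("chr1", "chr1"), c(0, 0), c(5000, 5000),
                   c(10000, 30000), c(15000, 35000))
  ms <- merge_loop_anchors(shared)
  expect_equal(nrow(ms), 3)
  expect_identical(oracle_covered(ms), oracle_covered(loop_anchors(shared)))
})

test_that("loop classification uses promoter and enhancer windows per anchor", {
  genes <- tibble::tibble(chrom = "chr1", start = 10000, end = 30000,
                          strand = "+", gene_id = "g1")
  enhancers <- gintervals("chr1", 101000, 101200) # window [101050, 101150)
  cfg <- run_config()
  ew <- enhancer_windows(enhancers, cfg)
  expect_equal(ew$start, 101050)
  expect_equal(ew$end, 101150)
  loops <- gloops(
    rep("chr1", 3),
    c(9000, 9000, 500000), c(14000, 10500, 505000),
    c(101000, 200000, 600000), c(106000, 205000, 605000))
  cl <- classify_loops(loops, enhancers, genes, cfg)
  expect_equal(cl$category,
               c("promoter-enhancer", "promoter-only", "neither"))
  # minus-strand promoter extends upstream of the gene span end
  gm <- tibble::tibble(chrom = "chr1", start = 10000, end = 30000,
                       strand = "-", gene_id = "g1")
  pw <- promoter_windows(gm, cfg)
  expect_equal(pw$start, 30000 - 5000)
  expect_equal(pw$end, 30000)
})

test_that("category odds ratios follow the two-proportion formula with exact Fisher p", {
  r <- category_odds_ratio(10, 100, 30, 100)
  expect_equal(r$ratio, 3.0)
  expect_equal(category_odds_ratio(10, 100, 10, 100)$ratio, 1.0)
  z <- category_odds_ratio(0, 100, 5, 100)
  expect_true(z$infinite)
  expect_equal(z$ratio, Inf)
  r2 <- category_odds_ratio(5, 100, 1, 100)
  expect_equal(r2$fisher_p, oracle_fisher_two_sided(1, 99, 5, 95),
               tolerance = 1e-10)
})
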