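test_that("gene bins follow the -4k/-2k/TSS, thirds, TTS/+2k/+4k scheme", {
  g <- tibble::tibble(chrom = "chr1", start = 10000, end = 13000,
                      strand = "+", gene_id = "g1")
  bins <- make_gene_bins(g)
  expect_equal(bins$start, c(6000, 8000, 10000, 11000, 12000, 13000, 15000))
  expect_equal(bins$end, c(8000, 10000, 11000, 12000, 13000, 15000, 17000))
  expect_equal(bins$bin, 1:7)
  # body bins tile the gene span exactly
  expect_equal(min(bins$start[3:5]), 10000)
  expect_equal(max(bins$end[3:5]), 13000)
})

test_that("minus-strand genes are mirrored and the remainder goes to the 3'-most body bin", {
  gm <- tibble::tibble(chrom = "chr1", start = 10000, end = 13000,
                       strand = "-", gene_id = "g1")
  bins <- make_gene_bins(gm)
  b <- bins[order(bins$bin), ]
  expect_equal(b$start[1], 15000) # most upstream = right of the gene
  expect_equal(b$end[1], 17000)
  expect_equal(b$start[3:5], c(12000, 11000, 10000))
  # remainder rule: body of 10 bp -> widths 3, 3, 4 in transcription order
  g10 <- tibble::tibble(chrom = "chr1", start = 10000, end = 10010,
                        strand = "+", gene_id = "g")
  w <- make_gene_bins(g10)
  expect_equal(w$end[3:5] - w$start[3:5], c(3, 3, 4))
  gm10 <- tibble::tibble(chrom = "chr1", start = 10000, end = 10010,
                         strand = "-", gene_id = "g")
  wm <- make_gene_bins(gm10)
  wm <- wm[order(wm$bin), ]
  expect_equal(wm$end[3:5] - wm$start[3:5], c(3, 3, 4))
  expect_error(make_gene_bins(tibble::tibble(chrom = "chr1", start = 0, end = 2,
                                             strand = "+", gene_id = "x")),
               "3 bp")
})

test_that("flank bins are clipped at chromosome ends and flagged", {
  g <- tibble::tibble(chrom = "chr1", start = 1000, end = 4000,
                      strand = "+", gene_id = "g1")
  bins <- make_gene_bins(g, genome = as_genome(c(chr1 = 5000)))
  expect_equal(bins$start[1], 0)
  expect_true(bins$clipped[1])
  expect_equal(bins$end[7], 5000)
  expect_true(all(bins$end >= bins$start))
})

test_that("occupancy bits mark >= 1 bp peak overlap per bin, half-open at boundaries", {
  g <- tibble::tibble(chrom = "chr1", start = 10000, end = 13000,
                      strand = "+", gene_id = "g1")
  bins <- make_gene_bins(g)
  none <- occupancy_bits(bins, gintervals("chr1", 0, 10))
  expect_equal(none$occupied, rep(0L, 7))
  spanning <- occupancy_bits(bins, gintervals("chr1", 9900, 10100))
  expect_equal(spanning$occupied, c(0, 1, 1, 0, 0, 0, 0))
  # a peak ending exactly at a bin start touches nothing in that bin
  boundary <- occupancy_bits(bins, gintervals("chr1", 7000, 8000))
  expect_equal(boundary$occupied, c(1, 0, 0, 0, 0, 0, 0))
})

test_that("the accessibility-difference predictor follows its closed form", {
  expect_equal(atac_diff(5, 5, 100), 0)
  expect_equal(atac_diff(0.99, 0.09, 3), 2)
  expect_equal(atac_diff(9, 1, 0), 0)
  set.seed(61)
  ko <- runif(50) * 10; wt <- runif(50) * 10; tot <- ko + wt
  expect_equal(atac_diff(ko, wt, tot),
               log10((ko + 0.01) / (wt + 0.01)) * log2(tot + 1))
  expect_true(all(sign(atac_diff(ko, wt, tot)) == sign(ko - wt) | tot == 0))
})

test_that("the assembled matrix matches a brute-force build on a small fixture", {
  b <- simulate_bundle(sim_config(n_genes = 50, n_chromosomes = 1,
                                  chrom_length = 10e6, n_factor_a_loops = 30,
                                  n_factor_b_loops = 40, n_peaks = 40,
                                  n_balanced_pairs = 10))
  m <- assemble_matrix(b$genes, b$expression, b$peaks, b$loops_a, b$loops_b,
                       b$loops_over, b$loops_under, b$enhancers,
                       b$track_wt, b$track_ko, genome = b$genome)
  expect_equal(nrow(m), 50)
  for (i in c(3, 17, 42)) {
    expect_equal(m$satb1_loop_count[i],
                 oracle_anchor_count(b$genes[i, ], b$loops_a))
    expect_equal(m$ctcf_loop_count[i],
                 oracle_anchor_count(b$genes[i, ], b$loops_b))
    expect_equal(m$h3k27ac_over_count[i],
                 oracle_anchor_count(b$genes[i, ], b$loops_over))
    expect_equal(m$h3k27ac_under_count[i],
                 oracle_anchor_count(b$genes[i, ], b$loops_under))
  }
  # a gene out of every loop set with no peak and flat signal -> all-zero row
  iso_genes <- tibble::tibble(chrom = "chr1", start = 50000, end = 56000,
                              strand = "+", gene_id = "iso")
  iso_expr <- tibble::tibble(gene_id = "iso", wt_count = 1, ko_count = 1,
                             log2fc = 0, fdr = NA_real_)
  flat <- as_track(tibble::tibble(chrom = "chr1", start = 0, end = 1e5, value = 2))
  no_loops <- gloops(character(), numeric(), numeric(), numeric(), numeric())
  m0 <- assemble_matrix(iso_genes, iso_expr, gintervals(character(), numeric(), numeric()),
                        no_loops, no_loops, no_loops, no_loops,
                        gintervals(character(), numeric(), numeric()), flat, flat)
  expect_true(all(m0[, !(names(m0) %in% c("gene_id"))] == 0))
})

test_that("a loop connecting a gene to an enhancer is counted as an enhancer link", {
  genes <- tibble::tibble(chrom = "chr1", start = 10000, end = 20000,
                          strand = "+", gene_id = "g")
  loop <- gloops("chr1", 12000, 17000, 100000, 105000)
  enh <- gintervals("chr1", 102000, 102200)
  expr <- tibble::tibble(gene_id = "g", wt_count = 1, ko_count = 1,
                         log2fc = 0, fdr = NA_real_)
  flat <- as_track(tibble::tibble(chrom = "chr1", start = 0, end = 2e5, value = 1))
  none <- gloops(character(), numeric(), numeric(), numeric(), numeric())
  m <- assemble_matrix(genes, expr, gintervals(character(), numeric(), numeric()),
                       loop, none, none, none, enh, flat, flat)
  expect_equal(m$satb1_enhancer_link_count, 1L)
  # enhancer far from both anchors: no link
  m2 <- assemble_matrix(genes, expr, gintervals(character(), numeric(), numeric()),
                        loop, none, none, none, gintervals("chr1", 150000, 150200),
                        flat, flat)
  expect_equal(m2$satb1_enhancer_link_count, 0L)
})

test_that("OLS recovers planted coefficients within 3 SE and rejects rank deficiency", {
  b <- simulate_bundle(sim_config())
  m <- assemble_matrix(b$genes, b$expression, b$peaks, b$loops_a, b$loops_b,
                       b$loops_over, b$loops_under, b$enhancers,
                       b$track_wt, b$track_ko, genome = b$genome)
  pred <- setdiff(names(m), c("gene_id", "log2fc"))
  beta <- withr::with_seed(70, round(runif(length(pred), -1, 1), 2))
  m2 <- m
  m2$log2fc <- as.matrix(m[pred]) %*% beta + withr::with_seed(71, rnorm(nrow(m)))
  fit <- fit_expression_model(m2)
  est <- fit$coefficients[match(pred, fit$coefficients$term), ]
  expect_true(all(abs(est$estimate - beta) <= 3 * est$std_error))
  # y = 0.8 * loop count + noise: targeted recovery of one coefficient
  m3 <- m
  m3$log2fc <- 0.8 * m$satb1_loop_count + withr::with_seed(72, rnorm(nrow(m)))
  fit3 <- fit_expression_model(m3)
  co <- fit3$coefficients[fit3$coefficients$term == "satb1_loop_count", ]
  expect_true(abs(co$estimate - 0.8) <= 3 * co$std_error)
  # a pure-noise column barely moves R squared
  m4 <- m3
  m4$noise <- withr::with_seed(73, rnorm(nrow(m)))
  expect_lt(abs(fit_expression_model(m4)$r_squared - fit3$r_squared), 0.01)
  # duplicated column -> error naming the collinear term
  m5 <- m3
  m5$dup <- m5$satb1_loop_count
  expect_error(fit_expression_model(m5), "collinear.*dup")
})

test_that("an all-zero response gives zero coefficients and zero R squared", {
  set.seed(74)
  m <- tibble::tibble(gene_id = sprintf("g%02d", 1:40),
                      x1 = rnorm(40), x2 = rnorm(40), log2fc = 0)
  fit <- fit_expression_model(m)
  expect_equal(fit$coefficients$estimate, rep(0, 3))
  expect_equal(fit$r_squared, 0)
  expect_equal(glance(fit)$r_squared, 0)
  expect_equal(nrow(tidy(fit)), 3)
})
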