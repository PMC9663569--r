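test_that("a loop contributes at most one anchor overlap per gene", {
  gene <- tibble::tibble(chrom = "chr1", start = 0, end = 300000,
                         strand = "+", gene_id = "g")
  both_anchors <- gloops("chr1", 10000, 15000, 200000, 205000)
  expect_equal(anchor_gene_count(gene, both_anchors), 1L)
  three <- gloops(rep("chr1", 3), c(1e4, 5e4, 9e4), c(1.5e4, 5.5e4, 9.5e4),
                  c(4e6, 5e6, 6e6), c(4.005e6, 5.005e6, 6.005e6))
  expect_equal(anchor_gene_count(gene, three), 3L)
  far <- gloops("chr1", 4e6, 4.005e6, 5e6, 5.005e6)
  expect_equal(anchor_gene_count(gene, far), 0L)
})

test_that("anchor counts match the brute-force triple iteration on random instances", {
  set.seed(60)
  g <- small_genome()
  genes <- rand_intervals(80, g, sample(1000:20000, 80, replace = TRUE))
  genes$gene_id <- sprintf("g%03d", 1:80)
  a1 <- rand_intervals(120, g, 5000)
  l <- gloops(a1$chrom, a1$start, a1$end,
              pmin(a1$start + 60000, genome_size_of(g, a1$chrom) - 5000),
              pmin(a1$start + 65000, genome_size_of(g, a1$chrom)))
  got <- anchor_gene_count(genes, l)
  want <- vapply(seq_len(80), function(i) oracle_anchor_count(genes[i, ], l),
                 numeric(1))
  expect_equal(got, as.integer(want))
})

test_that("linking score is over minus under, normalised per kbp", {
  gene <- tibble::tibble(chrom = "chr1", start = 10000, end = 12000,
                         strand = "+", gene_id = "g")
  mk <- function(n) {
    if (n == 0) return(gloops(character(), numeric(), numeric(), numeric(), numeric()))
    gloops(rep("chr1", n), 10000, 12000, 1e5 + (1:n) * 1e4, 1e5 + (1:n) * 1e4 + 5000)
  }
  r <- linking_score(gene, mk(3), mk(1))
  expect_equal(r$score, 2L)
  expect_equal(r$score_per_kb, 1.0)
  expect_equal(linking_score(gene, mk(2), mk(2))$score, 0L)
  r4 <- linking_score(gene, mk(4), mk(0))
  expect_equal(r4$score_per_kb, 2.0)
})

test_that("correlation is +/-1 for perfectly monotone relations and outlier removal only shrinks n", {
  genes <- tibble::tibble(chrom = "chr1", start = (0:19) * 1e4,
                          end = (0:19) * 1e4 + 5000, strand = "+",
                          gene_id = sprintf("g%02d", 1:20))
  scores <- tibble::tibble(gene_id = genes$gene_id, n_over = 0L, n_under = 0L,
                           score = -9:10, score_per_kb = (-9:10) / 5)
  expr <- tibble::tibble(gene_id = genes$gene_id, wt_count = 100, ko_count = 100,
                         log2fc = as.numeric(-9:10) / 3, fdr = NA_real_)
  up <- expression_linking_correlation(expr, scores)
  expect_equal(up$rho, 1)
  down <- expression_linking_correlation(
    dplyr::mutate(expr, log2fc = -log2fc), scores)
  expect_equal(down$rho, -1)
  # a huge score is removed as an influential outlier
  scores2 <- scores; scores2$score[20] <- 99L
  r2 <- expression_linking_correlation(expr, scores2)
  expect_equal(r2$n_outliers_removed, 1L)
  expect_equal(r2$n_used, 19L)
  # with an infinite threshold the unfiltered correlation is returned
  r3 <- expression_linking_correlation(expr, scores2,
                                       run_config(outlier_linking_threshold = Inf))
  expect_equal(r3$n_used, 20L)
  expect_equal(r3$rho, 1)
  expect_error(expression_linking_correlation(expr[1:2, ], scores), "fewer than 3")
})

test_that("a planted rank correlation of 0.6 is recovered within 0.05 at 2000 genes, and a null within 0.1", {
  b <- simulate_bundle(sim_config(linking_correlation = 0.6))
  sc <- linking_score(b$genes, b$loops_over, b$loops_under)
  r <- expression_linking_correlation(b$expression, sc)
  expect_lt(abs(r$rho - 0.6), 0.05)
  b0 <- simulate_bundle(sim_config(linking_correlation = 0,
                                   planted_log2fc_in_a_loops = 0))
  r0 <- expression_linking_correlation(
    b0$expression, linking_score(b0$genes, b0$loops_over, b0$loops_under))
  expect_lt(abs(r0$rho), 0.1)
})

test_that("stratified fits separate genes in and out of a loop set", {
  b <- simulate_bundle(sim_config(n_genes = 300, n_chromosomes = 2,
                                  chrom_length = 15e6, n_factor_a_loops = 60,
                                  n_factor_b_loops = 80, n_peaks = 50,
                                  n_balanced_pairs = 30))
  sc <- linking_score(b$genes, b$loops_over, b$loops_under)
  r <- expression_linking_correlation(b$expression, sc, genes = b$genes,
                                      stratify_loops = b$loops_a)
  expect_setequal(unique(r$data$stratum), c("in_loops", "not_in_loops"))
  expect_equal(nrow(r$fits), 2)
})

test_that("hypergeometric enrichment matches the enumerated pmf tail", {
  r <- hypergeometric_enrichment(paste0("g", 1:10), paste0("g", 6:15), 100)
  expect_equal(r$overlap, 5L)
  expect_equal(r$expected, 1)
  expect_equal(r$fold, 5)
  expect_equal(r$p_value, oracle_hyper_upper(5, 10, 100, 10), tolerance = 1e-12)
  # fold 1 when the overlap equals its expectation
  r1 <- hypergeometric_enrichment(paste0("g", 1:10), paste0("g", c(1, 11:19)), 100)
  expect_equal(r1$fold, 1)
  # exhaustive agreement across k for N <= 60
  for (N in c(20, 45, 60)) {
    K <- 8; n <- 10
    for (k in 0:min(K, n)) {
      q <- paste0("g", 1:n)
      cat_genes <- paste0("g", c(seq_len(k), n + seq_len(K - k)))
      got <- hypergeometric_enrichment(q, cat_genes, N)$p_value
      expect_equal(got, oracle_hyper_upper(k, K, N, n), tolerance = 1e-12)
    }
  }
  expect_error(hypergeometric_enrichment(paste0("g", 1:10), paste0("h", 1:10), 15),
               "universe")
})

test_that("signature filter keeps genes at least 2-fold above every other group mean", {
  m <- rbind(kept = c(DN1 = 4, DN2b = 4, DN3 = 4, DP = 10, CD4SP = 5, CD8SP = 5),
             dropped = c(4, 4, 4, 9, 5, 5),
             flat = c(5, 5, 5, 5, 5, 5))
  groups <- c(DN1 = "DN", DN2b = "DN", DN3 = "DN", DP = "DP",
              CD4SP = "SP", CD8SP = "SP")
  res <- signature_filter(m, groups,
                          list(DP = c("kept", "dropped", "flat")))
  expect_equal(res$DP, "kept")
  expect_error(signature_filter(m, groups[groups != "DP"],
                                list(DP = "kept")), "no subsets|absent")
})
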