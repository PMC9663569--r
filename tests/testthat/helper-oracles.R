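# Brute-force per-bp oracles, independent of the package's interval engine.

# bp shared by two intervals, by explicit base enumeration
oracle_overlap_bp <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(0)
  length(intersect(seq(s1, e1 - 1), seq(s2, e2 - 1)))
}

# set of covered bases per chromosome
oracle_covered <- function(x) {
  lapply(split(x, x$chrom), function(d) {
    sort(unique(unlist(mapply(function(s, e) seq(s, e - 1), d$start, d$end,
                              SIMPLIFY = FALSE))))
  })
}

# max per-bp overlap score of a query span against reference spans
oracle_overlap_score <- function(qs, qe, ref) {
  qbase <- seq(qs, qe - 1)
  best <- 0
  for (i in seq_len(nrow(ref))) {
    best <- max(best, length(intersect(qbase, seq(ref$start[i], ref$end[i] - 1))))
  }
  best / (qe - qs)
}

# loops with >= 1 anchor overlapping the gene, iterating every triple
oracle_anchor_count <- function(gene, loops) {
  hit <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2)) > 0
  n <- 0
  for (i in seq_len(nrow(loops))) {
    if (loops$chrom[i] != gene$chrom) next
    left <- hit(gene$start, gene$end, loops$start1[i], loops$end1[i])
    right <- hit(gene$start, gene$end, loops$start2[i], loops$end2[i])
    if (left || right) n <- n + 1
  }
  n
}

# hypergeometric upper-tail P(X >= k) from the pmf written out with choose()
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(pmf[ks >= k])
}

# two-sided Fisher exact p by enumerating all tables with the same margins
oracle_fisher_two_sided <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  as <- max(0, c1 - (N - r1)):min(r1, c1)
  pmf <- choose(c1, as) * choose(N - c1, r1 - as) / choose(N, r1)
  p_obs <- pmf[as == a]
  sum(pmf[pmf <= p_obs + 1e-12])
}

rand_intervals <- function(n, genome, width) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  s <- floor(runif(n) * (genome$size[ci] - width))
  gintervals(genome$chrom[ci], s, s + width)
}

small_genome <- function() as_genome(c(chr1 = 1e6, chr2 = 5e5))
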