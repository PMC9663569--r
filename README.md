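# loopstats

Loop-level statistics connecting 3D chromatin loops to gene regulation.

Protein-directed conformation assays (HiChIP) yield sets of chromatin loops
associated with a factor or histone mark — for example loops that depend on a
tissue-specific genome organizer versus loops scaffolded by CTCF, or H3K27ac
loops called differential (over- or under-interacting) between a knockout and
wild type. Connecting those loop sets to each other and to transcription
requires a family of bespoke interval statistics that sit downstream of loop
calling and upstream of biological interpretation. `loopstats` implements
that layer as a tidyverse-style R package: every function takes plain tibbles
of intervals, loops, genes or per-gene records and returns tibbles, so the
pieces compose with `dplyr` and pipe naturally.

## What it computes

* **Overlap / engulfment scoring.** For a query loop with span *S* (outer
  coordinates of its two anchors) and a reference loop set, the overlap score
  is max over reference spans *R* of |S ∩ R| / |S| — 1.0 means the query is
  fully engulfed in some reference loop, 0.0 means no overlap. Observed
  scores are compared with scores of the same loops randomly relocated across
  the genome (rigid spans: anchor sizes and gap conserved), with a two-sided
  Wilcoxon rank-sum p-value.
* **Transcriptional insulation.** For each loop, the absolute difference
  between the mean length-normalised expression score
  log10(counts / gene length + 0.01) of genes inside the span and of genes in
  equal-size flanking regions, against a shuffled-loop null in which
  gene-less placements are re-drawn.
* **Permutation and bootstrap enrichment.** Interval-overlap enrichment with
  the counting p-value p = (#rounds with permuted overlap > observed) / n;
  site-accessibility bootstrap on log10 mean signal over center ± 250 bp
  windows, p = (#permuted means > real mean) / n; the permutation-mean cutoff
  for picking low-accessibility binding sites.
* **Differential-loop linking.** Per-gene linking score = (# overinteracting
  − # underinteracting) loops with an anchor on the gene (each loop counted
  once), optionally per kbp of gene length; Spearman correlation with
  expression log2FC after removing |score| > 40 outliers; hypergeometric
  gene-set enrichment; the ≥ 2-fold cross-group filter for subset signature
  genes.
* **Expression-change regression.** Per-gene predictors — binary binding
  occupancy over seven bins (−4k/−2k/TSS, three body thirds, TTS/+2k/+4k, in
  transcription orientation), the accessibility difference
  log10((KO + 0.01)/(WT + 0.01)) · log2(Total + 1) per bin, structural
  loop-anchor counts, gene-to-enhancer loop links, differential-loop counts —
  fit by OLS against RNA log2FC, with `tidy()` / `glance()` accessors.
* **Accessibility profiles.** Per-bp log2FC(KO/WT) meta-profile around TSS
  (± 1 kbp, strand-oriented) and a binned profile across scaled gene bodies
  with fixed-width flanks.
* **Synthetic cohorts.** `simulate_bundle()` generates a full input bundle —
  chromosome sizes, disjoint stranded genes, a CTCF-like structural loop set,
  a smaller loop set nested inside it with controllable engulfment fraction,
  enhancers, binding sites with elevated accessibility, WT/KO signal tracks,
  negative-binomial expression with planted effects, and differential loops
  whose linking score is coupled to expression through a Gaussian copula on
  ranks — plus a truth table, so every statistic can be validated against
  ground truth. `write_bundle()` emits the standard plain-text formats (BED,
  BEDPE, bedGraph, chrom.sizes, TSV) read back by `read_bed()`,
  `read_bedpe_loops()`, `read_bedgraph()`, `read_expression_table()`.

## Worked example

```r
library(loopstats)

b <- simulate_bundle(sim_config())   # default synthetic cohort, seed 42

# are the small-factor loops engulfed in the structural loops?
d <- score_distribution(b$loops_a, b$loops_b, b$genome, seed = 1)
fraction_overlapping(b$loops_a, b$loops_b)

# do differential loops track expression change?
sc <- linking_score(b$genes, b$loops_over, b$loops_under)
r  <- expression_linking_correlation(b$expression, sc)

# is accessibility elevated at binding sites?
pa <- peak_accessibility_test(b$peaks, b$track_wt, b$genome, seed = 1, n = 100)

# model expression change from occupancy, accessibility and loop predictors
m   <- assemble_matrix(b$genes, b$expression, b$peaks, b$loops_a, b$loops_b,
                       b$loops_over, b$loops_under, b$enhancers,
                       b$track_wt, b$track_ko, genome = b$genome)
fit <- fit_expression_model(m)
glance(fit)
```

Output:

```
engulfment: median observed score 1.00 vs shuffled 0.00 (Wilcoxon p = 1.3e-95)
fraction of factor-A loops overlapping a factor-B loop: 0.94
linking-score vs log2FC: Spearman rho = 0.59 (n = 2000, outliers removed = 0)
site accessibility: real mean log10 score 1.00, bootstrap p = 0.00
# A tibble: 1 x 5
  r_squared adj_r_squared sigma     n df_residual
      <dbl>         <dbl> <dbl> <int>       <int>
1     0.379         0.373 0.583  2000        1980
```

Reading: the generator plants 90% engulfment, so observed scores pile at 1.0
while rigid-span shuffles of the same loops score ~0; the planted rank
coupling of 0.6 between differential looping and expression is recovered
(ρ = 0.59); binding sites carry 10× background signal, so no permuted mean
beats the real one and the bootstrap p is 0. Plots:
`plot_score_distribution(d)`, `plot_linking_correlation(r)`,
`autoplot(fit)`.

## Truth table

`simulate_bundle()` returns `truth`, one row per gene: `in_a_span` /
`in_a_anchor` (whether the gene overlaps a factor-A loop span / anchor),
`mu_baseline` (expected baseline counts, including the inside-loop shift),
`lfc_true` (planted expression log2FC) and `linking_score_true` (the planted
integer linking score realised by the generated differential loops).
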