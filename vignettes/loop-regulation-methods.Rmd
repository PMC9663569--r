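---
title: "Methods: loop-level statistics for regulatory chromatin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop-level statistics for regulatory chromatin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopstats)
```

This vignette documents the statistical procedures implemented in
`loopstats`, their assumptions, the tunable constants, the design decisions
taken where more than one reading was defensible, and what the synthetic-data
generator does and does not emulate.

## Coordinates and containers

All coordinates are 0-based, half-open (BED-native); conversions to the
1-based closed convention happen only inside the GenomicRanges adapter.
Intervals, loops, genes, signal tracks and expression records are plain
tibbles, so results flow through dplyr pipelines. A loop is a cis interaction
between two anchors; its *span* runs between the outer coordinates of the
anchors, and the span — not the anchor pair — is the unit of overlap scoring
and insulation. Signal tracks follow bedGraph semantics: sorted,
non-overlapping scored intervals with every uncovered base worth 0;
overlapping records are rejected because mean queries are only well defined
over a partition.

## Overlap and engulfment scoring

The score of a query loop against one reference loop is
(overlapping bp) / (bp size of the query loop), with the loop size taken as
the span length. Against a reference *set*, the maximum across reference
loops is kept, so 1.0 means the query span is fully contained (engulfed) in
some reference span and 0.0 means no overlap. We score spans rather than
anchor pairs because the engulfment question — is the fine loop nested inside
the coarse scaffold loop? — is a statement about the whole spanned region;
`fraction_overlapping()` uses the same span semantics so the two statistics
agree on what "overlapping" means.

The control distribution re-scores the same query loops after random
relocation. Loops move as rigid units: anchor lengths and the inter-anchor
gap are conserved and only the span's position changes, because the
downstream statistics treat a loop as one object; shuffling anchors
independently would destroy the length distribution that the score
denominators depend on. Placement draws a destination chromosome with
probability proportional to the number of valid start positions it offers and
then a uniform start, i.e. uniform over all valid placements genome-wide; a
`same_chrom` flag restricts placement to the source chromosome for users who
prefer a stratified null. Shuffled loops may overlap each other or the
originals — no exclusion is applied, matching the simplest exchangeable null.

## Transcriptional insulation

A loop's insulation score is |mean(inside) − mean(flank)| of the
length-normalised expression score `log10(counts / gene length + 0.01)`.
"Inside" collects genes overlapping the span by at least 1 bp; the flank
pools genes from the two same-size windows immediately left and right of the
span into a single mean (one pooled flank, not a per-side average), clipped
at chromosome ends. The ≥ 1 bp assignment rule is used everywhere a gene
meets a region in this package, for comparability. Loops with no inside or no
flank genes are flagged invalid rather than scored. The null relocates the
loops across the genome; any placement containing no gene is re-drawn (up to
1,000 attempts, then dropped with a warning) so that every null score is
defined; observed and pooled null scores are compared with a two-sided
Wilcoxon rank-sum test.

## Permutation and bootstrap tests

`permutation_overlap_test()` counts query intervals overlapping at least one
subject interval, relocates the query set `n_perm` times (default 1,000) and
reports `p = (#rounds with permuted count > observed) / n_perm`, exactly the
counting rule with strict inequality and divisor *n*. This estimator can
return 0 and is slightly anti-conservative under heavy ties; a
`conservative` flag switches to the standard (k+1)/(n+1) correction. The
default stays with the plain counting rule for fidelity to the procedure the
statistic reproduces; the type-I calibration in the test suite shows it holds
its nominal level when the overlap count is not dominated by discreteness
(hundreds of intervals, counts well away from 0).

`peak_accessibility_test()` scores each binding site as log10 of the mean
track signal over its central base ± 250 bp (a 501 bp window; a zero mean is
floored at the accessibility pseudocount 0.01 before the log, avoiding −∞ on
empty regions) and bootstraps the mean of those scores over 100 random
relocations, `p = (#permuted means > real mean) / 100`.
`low_accessibility_subset()` runs 10 relocation rounds and uses the average
of the per-round mean null scores as a cutoff: sites scoring below it form
the low-accessibility subset.

All randomised procedures take an explicit integer seed and are bit-identical
under it. The permutation inner loop evaluates all rounds at once against a
pre-merged subject index (a `findInterval()` scan); the test suite
cross-checks this engine against the GenomicRanges route and a per-bp
enumeration oracle.

## Linking differential loops to expression

The per-gene linking score is n_over − n_under, where each count is the
number of loops of that class with ≥ 1 anchor overlapping the gene span and a
loop contributes at most once even if both anchors hit the gene. The sign
convention is over − under, so positive scores mean gained interactions in
the perturbed condition; this keeps "positive correlation with expression
log2FC" reading naturally. Because short genes accumulate fewer anchors, a
per-kbp variant divides the score by gene length in kbp. Before correlating
with expression change, genes with |score| > 40 are removed as influential
outliers (the threshold is configurable and applies to the raw score);
Spearman's rank correlation is reported together with per-stratum
least-squares lines for plotting, stratified by membership in a supplied loop
set when given.

Hypergeometric enrichment uses the exact upper tail P(X ≥ k) with the
expected overlap taken as the mean of the hypergeometric background,
|query|·|category| / universe, and fold = observed / expected. The signature
filter keeps, within each cluster assigned to a group, genes whose mean
expression across the group's subsets is **at least** 2-fold ("≥",
inclusive) the mean of every other group; the comparison is group-mean
against group-mean (not against the per-subset maximum), the plainer reading
of a between-group fold filter, and the fold is configurable.

## The expression-change model

Each gene contributes seven bins in transcription orientation: upstream
(−4 kbp to −2 kbp from the TSS), promoter (−2 kbp to TSS), three equal-width
body bins, and TTS→+2 kbp, +2 kbp→+4 kbp. The body remainder goes to the
3′-most body bin (the split is otherwise unspecified by the procedure the
model reproduces); minus-strand genes are mirrored genomically so bin 1 is
always most upstream; flank bins are clipped at chromosome ends and flagged.
Per bin, occupancy is a 0/1 flag for ≥ 1 bp overlap with a binding site, and
the accessibility difference is
log10((KO + 0.01)/(WT + 0.01)) · log2(Total + 1). Two conventions here were
genuinely open and are therefore explicit parameters of the implementation:
per-bin "normalized reads" are the *mean* track signal over the bin (means
are invariant to bin width, unlike sums, so body bins of different genes are
comparable), and "Total" is taken as KO + WT for the bin. Loop predictors are
the anchor-overlap counts for the two structural factors, the count of loops
connecting the gene to an enhancer (one anchor on the gene, the other on an
enhancer window), and the over-/under-interacting counts. The fit is plain
OLS with an intercept; predictors are not standardised (coefficients stay in
their native units), a rank-deficient design is an error naming the collinear
columns, and an all-zero response is reported with R² = 0 by convention
(the total sum of squares vanishes).

## Promoters, enhancers, windows

A promoter is the TSS extended 5 kbp in the direction of transcription (into
the gene body). A one-sided downstream window was chosen because the gene
lists the model consumes are span-based and a downstream window keeps the
promoter inside the annotated gene; the extension length and the choice are
configurable (`promoter_extension`). Enhancer records are tested as their
center ± 50 bp (`enhancer_flank`); binding sites as center ± 250 bp with the
central base included (`peak_flank`; a width-1 site at position c yields
[c − 250, c + 251)). The TSS accessibility profile spans ± 1 kbp
(`tss_flank`), is strand-oriented (positive offsets downstream), uses per-bp
log2((KO + 0.01)/(WT + 0.01)) averaged over **all** genes, expressed or not.
The gene-body profile splits each body into `n_bins` equal bins (remainder to
the 3′-most) with fixed-width flank bins; genes shorter than `n_bins` bp are
skipped with a warning.

## The synthetic cohort

`sim_config()` fixes the study conditions the tests run under: a 4 × 200 Mbp
genome carrying 2,000 disjoint stranded genes (log-normal lengths, median
8 kbp); 800 structural factor-B loops with log-normal spans (median 400 kbp,
covering roughly 40% of the genome — the coverage the scaled-down loop counts
imply); 500 factor-A loops (median span 100 kbp) placed inside a random
factor-B span with probability `engulfment_fraction` = 0.9, else uniformly;
5 kbp anchors (the loop-calling resolution); 800 enhancers of which 30% sit
in factor-A right anchors; 2,000 binding sites of 600 bp carrying 10×
background accessibility in WT and half of that in KO
(`ko_accessibility_drop` = 0.5); negative-binomial expression
(variance = μ + μ²/10) around log-normal baselines, with genes inside
factor-A spans boosted 10× (an inside-vs-flank expression-score shift of 1)
and genes on factor-A anchors planted with log2FC −1 (repression in the
knockout, the direction of the effects the statistics are built to detect).
Differential loops realise an integer linking score per gene drawn from a
Gaussian copula on the ranks of the realised log2FC, with the latent Pearson
correlation set to 2·sin(π·ρ/6) so the population Spearman correlation equals
the requested `linking_correlation` (default 0.6); one loop is created per
score unit, with the off-gene anchor re-drawn up to 50 times to avoid other
genes so counts stay attributable, plus 200 score-neutral over/under pairs as
background. Tracks are emitted as run-length-encoded piecewise-constant
bedGraph records (one record per constant stretch), which preserves exact
per-bp query semantics at a fraction of the size of fixed-resolution binning.

What the generator deliberately does **not** emulate: read-level noise (no
FASTQ, no mapping artefacts), irregular chromosome sizes, overlapping or
nested genes, distance-dependent loop calling biases, blacklisted regions,
1D occupancy differences confounding the differential-loop labels, and
realistic genome annotation density. Passing tests therefore demonstrate
that each statistic recovers the effect it is defined to measure under a
clean generative model — not that the surrounding upstream processing
(loop calling, peak calling, count normalisation) is reproduced.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence checks at 1,000 genes × 1,000
loops with vectorised brute-force enumeration; the permutation type-I
calibration uses 500 null data sets of 200 × 5 kbp intervals on a 10 Mbp
chromosome at 200 permutations each (the empirical rejection rate at
α = 0.05 must fall inside the binomial 95% interval); insulation detection
uses a 20 Mbp chromosome with 400 genes and 80 loops over 30 shuffle rounds;
OLS and linking recovery run at the full default cohort of 2,000 genes.
Exact equalities are asserted where arithmetic is exact (scores 1.0/0.0,
counting p-values on the k/n grid, byte-identical bundle regeneration);
stochastic recoveries use the tolerances stated above (3 standard errors for
coefficients, ±0.05 for the planted rank correlation).

Degenerate inputs are handled explicitly: empty reference sets score 0;
empty tracks are an error where a signal is required and an all-zero track
otherwise; zero-width clipped bins contribute zero occupancy and zero
accessibility difference; loops whose insulation regions contain no genes
are flagged, not scored; intervals longer than every chromosome cannot be
shuffled and raise an error naming the offending row.

## Limitations

The package consumes loop calls, binding sites, normalised tracks and
differential-expression tables; it does not produce them. P-values from the
counting formulas are granular at 1/n and can be exactly 0 — use the
`conservative` flag when downstream multiplicity control needs strictly
positive p-values. The linking-score outlier threshold and the promoter
window direction encode specific analysis conventions; both are parameters,
and conclusions sensitive to them should be checked across settings.
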