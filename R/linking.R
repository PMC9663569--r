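#' Count loops with an anchor overlapping each gene
#'
#' A gene collects one count per loop with at least one anchor overlapping the
#' gene span (>= 1 bp); when both anchors of the same loop overlap the gene,
#' only one is counted.
#'
#' @param genes Gene tibble.
#' @param loops Loop tibble.
#' @return Integer vector, one count per gene.
#' @export
anchor_gene_count <- function(genes, loops) {
  if (nrow(loops) == 0 || nrow(genes) == 0) return(integer(nrow(genes)))
  anch <- loop_anchors(loops)
  hits <- overlap_pairs(genes, anch)
  hits$loop <- anch$loop_id[hits$subject]
  hits <- dplyr::distinct(hits, .data$query, .data$loop)
  out <- integer(nrow(genes))
  tab <- table(hits$query)
  out[as.integer(names(tab))] <- as.integer(tab)
  out
}

#' Per-gene differential-loop linking scores
#'
#' The linking score of a gene is the number of overinteracting loops minus
#' the number of underinteracting loops whose anchors overlap the gene
#' (positive = gained interactions in the knockout). `score_per_kb`
#' normalises the score to the gene length in kbp so that short genes are not
#' underestimated.
#'
#' @param genes Gene tibble.
#' @param over_loops,under_loops Loop tibbles of over-/under-interacting loops.
#' @return Tibble with `gene_id`, `n_over`, `n_under`, `score`,
#'   `score_per_kb`.
#' @export
linking_score <- function(genes, over_loops, under_loops) {
  n_over <- anchor_gene_count(genes, over_loops)
  n_under <- anchor_gene_count(genes, under_loops)
  tibble::tibble(gene_id = genes$gene_id,
                 n_over = n_over, n_under = n_under,
                 score = n_over - n_under,
                 score_per_kb = (n_over - n_under) / ((genes$end - genes$start) / 1000))
}

#' Correlation between expression change and linking score
#'
#' Spearman rank correlation between per-gene `log2fc` and the linking score
#' (or its per-kb version), after removing genes with
#' `|score| > outlier_linking_threshold` as influential outliers. A
#' least-squares line of `log2fc` on the score is also fitted for plotting,
#' stratified by membership in `stratify_loops` anchors when supplied.
#'
#' @param expression Expression tibble.
#' @param scores Output of [linking_score()].
#' @param config A [run_config()]; `outlier_linking_threshold` applies to the
#'   raw (not per-kb) score.
#' @param per_kb Correlate the length-normalised score instead?
#' @param genes,stratify_loops Optional: gene tibble plus a loop set whose
#'   anchor membership splits the fitted lines into two strata.
#' @return List with `rho`, `p_value`, `n_used`, `n_outliers_removed`,
#'   the per-gene `data` tibble, and a `fits` tibble of per-stratum
#'   least-squares intercept/slope.
#' @export
expression_linking_correlation <- function(expression, scores,
                                           config = run_config(),
                                           per_kb = FALSE,
                                           genes = NULL, stratify_loops = NULL) {
  d <- dplyr::inner_join(expression, scores, by = "gene_id")
  out_flag <- abs(d$score) > config$outlier_linking_threshold
  n_out <- sum(out_flag)
  d <- d[!out_flag, , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 genes after outlier removal")
  d$x <- if (per_kb) d$score_per_kb else d$score
  ct <- suppressWarnings(stats::cor.test(d$x, d$log2fc, method = "spearman"))
  d$stratum <- "all"
  if (!is.null(genes) && !is.null(stratify_loops)) {
    member <- anchor_gene_count(genes, stratify_loops) > 0
    d$stratum <- ifelse(member[match(d$gene_id, genes$gene_id)],
                        "in_loops", "not_in_loops")
  }
  fits <- purrr::map_dfr(split(d, d$stratum), function(s) {
    co <- stats::coef(stats::lm(log2fc ~ x, data = s))
    tibble::tibble(stratum = s$stratum[1], intercept = co[[1]], slope = co[[2]],
                   n = nrow(s))
  })
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_used = nrow(d),
       n_outliers_removed = n_out, data = d, fits = fits)
}

#' Hypergeometric enrichment of a gene set in a category
#'
#' Overlap `k` between a query set and a category set drawn from a universe of
#' `universe_size` genes; the expected overlap is the mean of the
#' hypergeometric background distribution (`|query| * |category| / universe`),
#' fold = k / expected, and the p-value is the upper tail `P(X >= k)`.
#'
#' @param query_genes,category_genes Character vectors of gene identifiers.
#' @param universe_size Number of genes in the universe.
#' @return One-row tibble: `overlap`, `expected`, `fold`, `p_value`,
#'   `fold_defined`.
#' @export
hypergeometric_enrichment <- function(query_genes, category_genes,
                                      universe_size) {
  q <- unique(query_genes); cat <- unique(category_genes)
  k <- length(intersect(q, cat))
  if (universe_size < length(q) + length(cat) - k) {
    stop("universe smaller than the union of the two sets")
  }
  expected <- length(q) * length(cat) / universe_size
  p <- stats::phyper(k - 1, length(cat), universe_size - length(cat),
                     length(q), lower.tail = FALSE)
  tibble::tibble(overlap = k, expected = expected,
                 fold = if (expected > 0) k / expected else NA_real_,
                 p_value = p, fold_defined = expected > 0)
}

#' Subset signature genes by cross-group fold change
#'
#' Given a gene-by-subset matrix of normalised expression, a mapping of
#' subsets to groups (e.g. DN/DP/SP developmental stages) and cluster
#' memberships assigning each cluster to a group, keeps as signature genes of
#' group G those cluster members whose mean expression across G's subsets is
#' at least `fold` times the mean expression of every other group.
#'
#' @param subset_matrix Numeric matrix or data frame, genes in rows (row
#'   names = gene ids), subsets in columns.
#' @param groups Named character vector: subset (column) name -> group name.
#' @param cluster_members Named list: group name -> character vector of gene
#'   ids (the manually selected cluster for that group).
#' @param fold Required fold difference (default 2, inclusive).
#' @return Named list: group -> character vector of retained signature genes.
#' @export
signature_filter <- function(subset_matrix, groups, cluster_members, fold = 2) {
  m <- as.matrix(subset_matrix)
  if (any(m < 0)) stop("expression matrix must be non-negative")
  gnames <- unique(groups)
  if (!all(names(groups) %in% colnames(m))) {
    stop("groups name subsets absent from the matrix")
  }
  group_means <- vapply(gnames, function(g) {
    cols <- names(groups)[groups == g]
    if (length(cols) == 0) stop("group with no subsets: ", g)
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(group_means) <- rownames(m)
  missing_groups <- setdiff(names(cluster_members), gnames)
  if (length(missing_groups)) {
    stop("group with no subsets: ", paste(missing_groups, collapse = ", "))
  }
  lapply(stats::setNames(names(cluster_members), names(cluster_members)),
         function(g) {
    ids <- intersect(cluster_members[[g]], rownames(m))
    if (length(ids) == 0) return(character(0))
    own <- group_means[ids, g]
    others <- group_means[ids, setdiff(gnames, g), drop = FALSE]
    ids[own >= fold * apply(others, 1, max)]
  })
}
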