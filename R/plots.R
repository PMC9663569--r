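#' Violin plot of observed vs shuffled overlap scores
#'
#' @param dist Output of [score_distribution()].
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(dist) {
  ggplot2::ggplot(dist$scores,
                  ggplot2::aes(x = .data$set, y = .data$overlap_score,
                               fill = .data$set)) +
    ggplot2::geom_violin(scale = "width") +
    ggplot2::geom_boxplot(width = 0.1, fill = "white", outlier.shape = NA) +
    ggplot2::labs(x = NULL, y = "overlap score",
                  subtitle = paste("Wilcoxon p =", format(dist$p_value, digits = 3))) +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
}

#' Accessibility profile line plot
#'
#' @param profile Output of [tss_profile()] (columns `offset`, `log2fc`) or
#'   [gene_body_profile()] (columns `bin`, `log2fc`).
#' @return A ggplot object.
#' @export
plot_profile <- function(profile) {
  xvar <- if ("offset" %in% names(profile)) "offset" else "bin"
  ggplot2::ggplot(profile, ggplot2::aes(x = .data[[xvar]], y = .data$log2fc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(y = "mean log2FC accessibility (KO vs WT)") +
    ggplot2::theme_classic()
}

#' Linking-score vs expression-change scatter
#'
#' Scatter of per-gene expression change against the differential-loop linking
#' score, with the per-stratum least-squares lines.
#'
#' @param corr Output of [expression_linking_correlation()].
#' @return A ggplot object.
#' @export
plot_linking_correlation <- function(corr) {
  ggplot2::ggplot(corr$data,
                  ggplot2::aes(x = .data$x, y = .data$log2fc,
                               colour = .data$stratum)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(data = corr$fits,
                         ggplot2::aes(intercept = .data$intercept,
                                      slope = .data$slope,
                                      colour = .data$stratum)) +
    ggplot2::labs(x = "linking score (over - under)", y = "expression log2FC",
                  subtitle = paste0("Spearman rho = ",
                                    format(corr$rho, digits = 3))) +
    ggplot2::theme_classic()
}

#' Coefficient plot for the expression-change model
#'
#' @param object An `expression_model`.
#' @param ... Unused.
#' @return A ggplot object (estimates with 95% normal intervals).
#' @method autoplot expression_model
#' @export
autoplot.expression_model <- function(object, ...) {
  d <- object$coefficients[object$coefficients$term != "(Intercept)", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate,
                                  y = stats::reorder(.data$term, .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error), height = 0.2) +
    ggplot2::labs(x = "coefficient", y = NULL) +
    ggplot2::theme_classic()
}
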