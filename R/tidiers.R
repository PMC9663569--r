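#' Tidy a fitted object into a tibble
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A tibble with one row per model term.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#'
#' @param x A fitted object.
#' @param ... Passed to methods.
#' @return A one-row tibble of fit statistics.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
tidy.expression_model <- function(x, ...) x$coefficients

#' @rdname glance
#' @export
glance.expression_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 sigma = summary(x$fit)$sigma, n = x$n,
                 df_residual = x$fit$df.residual)
}
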