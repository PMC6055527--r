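# ggplot2 views of calling results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot junction allele fractions by conventional annotation class
#'
#' @param object An `scm_calls` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scm_calls
#' @export
autoplot.scm_calls <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$variant_class, y = .data$jaf)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1.2,
                         ggplot2::aes(colour = .data$review)) +
    ggplot2::labs(x = "conventional annotation", y = "junction allele fraction",
                  colour = "review") +
    ggplot2::theme_minimal()
}

#' Plot reference vs mutant splice scores of the alternative site
#'
#' Each point is one call; points above the diagonal gained splice-site
#' strength after mutation.
#'
#' @param x An `scm_calls` object or calls tibble.
#' @return A ggplot.
#' @export
plot_score_shift <- function(x) {
  calls <- if (inherits(x, "scm_calls")) x$calls else tibble::as_tibble(x)
  calls <- calls[!is.na(calls$alt_ref_score), , drop = FALSE]
  ggplot2::ggplot(calls,
                  ggplot2::aes(x = .data$alt_ref_score,
                               y = .data$alt_mut_score,
                               colour = .data$variant_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "reference splice score (bits)",
                  y = "mutant splice score (bits)",
                  colour = "annotation") +
    ggplot2::theme_minimal()
}

#' Plot per-gene recurrence of Pass calls
#'
#' @param object An `scm_recurrence` object.
#' @param top Show the `top` most recurrent genes.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot scm_recurrence
#' @export
autoplot.scm_recurrence <- function(object, top = 20, ...) {
  g <- utils::head(object$gene_counts, top)
  g$gene <- factor(g$gene, levels = rev(g$gene))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$n_calls, y = .data$gene)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Pass calls", y = NULL) +
    ggplot2::theme_minimal()
}
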