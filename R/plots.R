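#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of the canonical scores of one mode
#'
#' @param object A `cca_fit`.
#' @param mode Mode index.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cca_fit <- function(object, mode = 1, ...) {
  df <- tibble::tibble(genetic = object$scores_u[, mode],
                       connectomic = object$scores_v[, mode])
  ggplot2::ggplot(df, ggplot2::aes(.data$genetic, .data$connectomic)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::labs(
      x = "genetic canonical score", y = "connectomic canonical score",
      title = sprintf("Mode %d, canonical r = %.2f", mode, object$r[mode])
    ) +
    ggplot2::theme_minimal()
}

#' Incremental R-squared profile of a PRS threshold scan
#'
#' @param object A `prs_result`.
#' @param ... Unused.
#' @return A ggplot of delta R^2 against the p-value threshold (log scale).
#' @export
autoplot.prs_result <- function(object, ...) {
  df <- object$profile[!is.na(object$profile$delta_r2), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$delta_r2)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inclusion p-value threshold",
                  y = expression(Delta * R^2),
                  title = "Polygenic score threshold scan") +
    ggplot2::theme_minimal()
}

#' Distribution of canonical strengths by block
#'
#' Histograms of the per-feature canonical strengths, split by block and
#' shaded by FDR significance.
#'
#' @param strengths Tibble from [strength_table()].
#' @param q_threshold Significance threshold for the shading.
#' @return A ggplot.
#' @export
plot_strengths <- function(strengths, q_threshold = 0.05) {
  df <- strengths[!is.na(strengths$strength), ]
  df$significant <- !is.na(df$q) & df$q < q_threshold
  ggplot2::ggplot(df, ggplot2::aes(.data$strength, fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 60, position = "stack") +
    ggplot2::facet_wrap(~ .data$block, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = sprintf("q < %g", q_threshold)) +
    ggplot2::labs(x = "canonical strength (feature-score correlation)",
                  y = "features") +
    ggplot2::theme_minimal()
}
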