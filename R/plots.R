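# ggplot2 views of the cohort results.

#' Plot a correlation battery
#'
#' Horizontal bars of Spearman's rho for every feature against the
#' composition-bias score, shaded by the significance convention met.
#'
#' @param object A `cohort_battery` from [correlation_battery()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_battery
#' @export
autoplot.cohort_battery <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    significance = dplyr::case_when(
      significant_strict ~ "strict",
      significant ~ "p < 0.05",
      TRUE ~ "n.s."),
    feature = stats::reorder(.data$feature, .data$rho))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$feature,
                                   fill = .data$significance)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Spearman rho vs composition-bias score", y = NULL,
                  fill = "significance") +
    ggplot2::theme_minimal()
}

#' Per-phylum score distributions
#'
#' Box-and-whisker plot of the composition-bias score by phylum, the
#' boxplot view of the phylum summary table.
#'
#' @param features Feature table with `phylum` and `score` columns.
#' @return A ggplot object.
#' @export
plot_phylum_scores <- function(features) {
  df <- dplyr::filter(tibble::as_tibble(features), !is.na(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$phylum,
                                                      .data$score,
                                                      FUN = stats::median),
                                   y = .data$score)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "composition-bias score") +
    ggplot2::theme_minimal()
}

#' Score against one feature
#'
#' Scatter plot of the composition-bias score against a chosen feature
#' column, with a monotone trend line.
#'
#' @param features Feature table.
#' @param feature Name of the feature column.
#' @return A ggplot object.
#' @export
plot_score_vs <- function(features, feature) {
  stopifnot(feature %in% names(features))
  ggplot2::ggplot(tibble::as_tibble(features),
                  ggplot2::aes(x = .data[[feature]], y = .data$score)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::labs(x = feature, y = "composition-bias score") +
    ggplot2::theme_minimal()
}
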