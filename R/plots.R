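# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot TRF weights over lags
#'
#' Channel-averaged kernel amplitude per predictor as a function of lag.
#'
#' @param object a `trf_model`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.trf_model <- function(object, ...) {
  td <- tidy(object) |>
    dplyr::group_by(.data$lag_ms, .data$predictor) |>
    dplyr::summarise(weight = mean(.data$weight), .groups = "drop")
  ggplot2::ggplot(td, ggplot2::aes(.data$lag_ms, .data$weight,
    group = .data$predictor)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "lag (ms)", y = "TRF weight (channel mean)",
      title = paste(object$tags, collapse = "+")) +
    ggplot2::theme_minimal()
}

#' Cross-validation curve: accuracy against the ridge parameter
#'
#' @param object a `trf_cv`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.trf_cv <- function(object, ...) {
  ggplot2::ggplot(object$lambda_summary,
    ggplot2::aes(.data$lambda, .data$mean_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(lambda), y = "mean r") +
    ggplot2::theme_minimal()
}

#' Unique predictive power by feature space and attention condition
#'
#' Box plots of the per-subject channel-averaged partial correlations.
#'
#' @param unique_tbl tibble from [unique_contribution()] (or the `unique`
#'   table of [run_study()] results).
#' @return A ggplot.
#' @export
plot_unique_contribution <- function(unique_tbl) {
  ggplot2::ggplot(unique_tbl, ggplot2::aes(.data$feature_space,
    .data$partial_r, fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "feature space", y = "unique partial r",
      fill = NULL) +
    ggplot2::theme_minimal()
}

#' Lag-windowed unique contribution
#'
#' @param windowed_tbl tibble from [windowed_unique_contribution()].
#' @return A ggplot.
#' @export
plot_windowed_contribution <- function(windowed_tbl) {
  wt <- windowed_tbl |>
    dplyr::mutate(window = sprintf("%g-%g", .data$win_lo, .data$win_hi))
  wt$window <- factor(wt$window, levels = unique(wt$window))
  ggplot2::ggplot(wt, ggplot2::aes(.data$window, .data$partial_r,
    fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "lag window (ms)", y = "unique partial r",
      fill = NULL) +
    ggplot2::theme_minimal()
}
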