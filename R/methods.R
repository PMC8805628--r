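# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted TRF model
#'
#' One row per (lag, predictor, channel) weight.
#'
#' @param x a `trf_model`.
#' @param ... unused.
#' @return A tibble with `lag_ms`, `predictor`, `channel`, `weight`.
#' @export
tidy.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  lags <- lag_samples(x$lag_ms[1], x$lag_ms[2], x$fs) / x$fs * 1000
  tibble::tibble(
    lag_ms = rep(lags, times = d[2] * d[3]),
    predictor = rep(rep(x$predictors, each = d[1]), times = d[3]),
    channel = rep(x$channels, each = d[1] * d[2]),
    weight = as.vector(x$weights)
  )
}

#' @rdname tidy.trf_model
#' @export
glance.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  tibble::tibble(
    lambda = x$lambda, n_lags = d[1], n_predictors = d[2],
    n_channels = d[3], lag_min_ms = x$lag_ms[1], lag_max_ms = x$lag_ms[2],
    tags = paste(x$tags, collapse = "+")
  )
}

#' Tidy a cross-validation result
#'
#' `tidy()` returns the per-lambda, per-trial, per-channel correlations;
#' `glance()` the selected lambda and its mean accuracy.
#'
#' @param x a `trf_cv`.
#' @param ... unused.
#' @export
tidy.trf_cv <- function(x, ...) x$scores

#' @rdname tidy.trf_cv
#' @export
glance.trf_cv <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, mean_r = x$mean_r, n_trials = x$n_trials,
    n_channels = length(x$channels), tags = paste(x$tags, collapse = "+")
  )
}

#' @rdname tidy.trf_cv
#' @export
tidy.trf_study_results <- function(x, ...) x$stat_report

#' @rdname tidy.trf_cv
#' @export
glance.trf_study_results <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$per_space$subject)),
    n_spaces = length(unique(x$per_space$space)),
    n_comparisons = nrow(x$stat_report),
    windowed = !is.null(x$windowed)
  )
}
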