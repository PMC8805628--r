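# Forward TRF estimation: lagged design matrices, ridge-regression reverse
# correlation solved jointly over channels, per-trial fitting with
# cross-trial averaging, and leave-one-trial-out cross-validation of the
# ridge parameter.

#' Default regularization grids
#'
#' `lambda_grid_decades()` is the model-comparison grid (decades from 1e-1
#' to 1e6); `lambda_grid_powers2()` is the finer grid used on the
#' partial-correlation path (powers of two from 2^-2 to 2^37).
#'
#' @return Numeric vector of ridge parameters, ascending.
#' @export
lambda_grid_decades <- function() 10^seq(-1, 6)

#' @rdname lambda_grid_decades
#' @export
lambda_grid_powers2 <- function() 2^seq(-2, 37)

# Integer lag samples for a [lag_min, lag_max] ms window at rate fs:
# inclusive of both ends, ceil on the lower edge and floor on the upper so
# adjacent windows tile without sharing samples.
lag_samples <- function(lag_min_ms, lag_max_ms, fs) {
  lo <- ceiling(lag_min_ms * fs / 1000 - 1e-9)
  hi <- floor(lag_max_ms * fs / 1000 + 1e-9)
  if (lo > hi) abort_bad_arg("lag window contains no integer lag.")
  seq.int(lo, hi)
}

# Workhorse: T x (npred * nlag) design from a predictors x T matrix.
# Column (p, tau) at row t holds predictor p at sample t - tau; rows with
# t - tau < 1 are zero. Lag varies fastest within each predictor block.
lag_design <- function(data, lags) {
  n_t <- ncol(data)
  npred <- nrow(data)
  nlag <- length(lags)
  out <- matrix(0, n_t, npred * nlag)
  for (p in seq_len(npred)) {
    x <- data[p, ]
    for (j in seq_len(nlag)) {
      tau <- lags[j]
      col <- (p - 1L) * nlag + j
      if (tau < n_t) {
        out[(tau + 1L):n_t, col] <- x[seq_len(n_t - tau)]
      }
    }
  }
  out
}

#' Lagged design matrix for TRF estimation
#'
#' Expands a feature set (or a list of feature sets, stacked for joint
#' models) into the time-lagged design matrix S used by the forward model:
#' one column per predictor and integer lag, rows aligned 1:1 with EEG
#' samples, out-of-range samples zero-padded. Lag samples run from
#' `ceil(lag_min * fs / 1000)` to `floor(lag_max * fs / 1000)` inclusive.
#'
#' @param features a [feature_set()] or list of them.
#' @param lag_min,lag_max lag window in milliseconds (default 0-300).
#' @return A `lagged_design`: list with `matrix`, `lags` (samples),
#'   `lag_ms`, `fs`, `tags`, `predictors`.
#' @export
lag_matrix <- function(features, lag_min = 0, lag_max = 300) {
  if (lag_min > lag_max) abort_bad_arg("`lag_min` must be <= `lag_max`.")
  st <- stack_features(features)
  lags <- lag_samples(lag_min, lag_max, st$fs)
  if (max(lags) >= ncol(st$data)) {
    abort_bad_arg("lag window is longer than the trial.")
  }
  structure(
    list(
      matrix = lag_design(st$data, lags),
      lags = lags, lag_ms = c(lag_min, lag_max), fs = st$fs,
      tags = st$tags, predictors = st$names
    ),
    class = "lagged_design"
  )
}

new_trf_model <- function(weights, lambda, lag_ms, fs, tags, predictors,
                          channels) {
  structure(
    list(
      weights = weights, lambda = lambda, lag_ms = lag_ms, fs = fs,
      tags = tags, predictors = predictors, channels = channels
    ),
    class = "trf_model"
  )
}

#' @export
print.trf_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf(
    "<trf_model [%s]>  %d lags x %d predictors x %d channels; lambda = %g; lags %g-%g ms\n",
    paste(x$tags, collapse = "+"), d[1], d[2], d[3], x$lambda,
    x$lag_ms[1], x$lag_ms[2]
  ))
  invisible(x)
}

#' Ridge-regression reverse correlation
#'
#' Solves the regularized normal equations `w = (S'S + lambda I)^-1 S' r`
#' jointly for all EEG channels (one shared `S'S`). With `lambda = 0` a
#' rank-deficient `S'S` raises an explicit singularity error.
#'
#' @param design a `lagged_design` from [lag_matrix()].
#' @param response an [eeg_recording()] or a samples x channels matrix.
#' @param lambda ridge parameter (>= 0).
#' @return A `trf_model` with `weights` of dimension lags x predictors x
#'   channels.
#' @export
ridge_fit <- function(design, response, lambda) {
  stopifnot(inherits(design, "lagged_design"))
  stopifnot_scalar_number(lambda, "lambda", min = 0)
  chan_names <- NULL
  if (inherits(response, "eeg_recording")) {
    chan_names <- response$labels
    response <- t(response$data)
  }
  if (nrow(response) != nrow(design$matrix)) {
    abort_bad_arg("design and response sample counts differ.")
  }
  chan_names <- chan_names %||% colnames(response) %||%
    sprintf("CH%02d", seq_len(ncol(response)))
  xtx <- crossprod(design$matrix)
  xty <- crossprod(design$matrix, response)
  a <- xtx
  diag(a) <- diag(a) + lambda
  w <- tryCatch(
    solve(a, xty),
    error = function(e) {
      rlang::abort(
        "S'S + lambda*I is singular; use lambda > 0 for rank-deficient designs.",
        class = c("speechtrf_error_singular", "speechtrf_error")
      )
    }
  )
  nlag <- length(design$lags)
  npred <- length(design$predictors)
  new_trf_model(
    weights = array(w, dim = c(nlag, npred, ncol(response))),
    lambda = lambda, lag_ms = design$lag_ms, fs = design$fs,
    tags = design$tags, predictors = design$predictors,
    channels = chan_names
  )
}

#' Predict EEG from a fitted TRF
#'
#' Computes `S w` for each channel, where `S` is the lagged design built
#' from `features` with the model's lag window. Feature-space tags must
#' match the model's. Predictors are z-scored per trial when
#' `normalize = TRUE` (the convention used during fitting).
#'
#' @param model a `trf_model`.
#' @param features a [feature_set()] or list of them (for joint models).
#' @param normalize z-score the predictors before prediction.
#' @return Channels x samples matrix of predicted EEG.
#' @export
predict_response <- function(model, features, normalize = TRUE) {
  stopifnot(inherits(model, "trf_model"))
  st <- stack_features(features)
  if (!identical(unname(st$tags), unname(model$tags))) {
    rlang::abort(
      sprintf("feature tags (%s) do not match model tags (%s).",
        paste(st$tags, collapse = "+"), paste(model$tags, collapse = "+")),
      class = c("speechtrf_error_tag_mismatch", "speechtrf_error")
    )
  }
  dat <- if (normalize) zscore_rows(st$data) else st$data
  lags <- lag_samples(model$lag_ms[1], model$lag_ms[2], st$fs)
  s <- lag_design(dat, lags)
  d <- dim(model$weights)
  w <- matrix(model$weights, nrow = d[1] * d[2])
  t(s %*% w)
}

#' Mean prediction accuracy over a channel subset
#'
#' Arithmetic mean of per-channel correlations over a named subset (e.g. a
#' fronto-temporal selection) or over all channels.
#'
#' @param r named numeric vector of per-channel correlations, or a tibble
#'   with columns `channel` and `r`.
#' @param channels character vector of channel labels, or `NULL` for all.
#' @return Scalar mean correlation.
#' @export
channel_mean_score <- function(r, channels = NULL) {
  if (is.data.frame(r)) r <- stats::setNames(r$r, r$channel)
  if (is.null(channels)) return(mean(r))
  if (length(channels) == 0L) abort_bad_arg("empty channel subset.")
  missing <- setdiff(channels, names(r))
  if (length(missing) > 0L) {
    abort_bad_arg(sprintf("unknown channel label(s): %s",
      paste(missing, collapse = ", ")))
  }
  mean(r[channels])
}

# Internal single-trial sufficient statistics for the ridge path:
# eigendecomposition of S'S plus Q'S'Y, from which w(lambda) is cheap for
# any lambda.
trial_suffstats <- function(features, eeg, lags, normalize = TRUE) {
  st <- stack_features(features)
  dat <- if (normalize) zscore_rows(st$data) else st$data
  x <- lag_design(dat, lags)
  y <- t(eeg$data)
  y <- sweep(y, 2L, colMeans(y)) # demean each channel per trial
  e <- eigen(crossprod(x), symmetric = TRUE)
  list(
    q = e$vectors, d = pmax(e$values, 0),
    b = crossprod(e$vectors, crossprod(x, y)),
    x = x, y = y
  )
}

ridge_weights_from_stats <- function(ss, lambda) {
  ss$q %*% (ss$b / (ss$d + lambda))
}

#' Leave-one-trial-out cross-validation of the ridge parameter
#'
#' Implements the per-trial estimation scheme: a separate TRF is fit on
#' each training trial, the training TRFs are averaged, and the average
#' model predicts the held-out trial; this is rotated over all trials. The
#' selected lambda maximizes the Pearson correlation between predicted and
#' actual EEG averaged over all trials and all channels (ties broken
#' toward the smaller lambda). One lambda is selected per subject.
#'
#' @param features list (one element per trial) of [feature_set()]s or
#'   lists of feature sets (joint models).
#' @param eeg list of [eeg_recording()]s, one per trial.
#' @param lambda numeric grid of ridge parameters.
#' @param lag_min,lag_max lag window in ms.
#' @param normalize z-score predictors and demean EEG per trial.
#'
#' @return A `trf_cv` object: `scores` (tibble lambda x trial x channel),
#'   `lambda_summary`, selected `lambda`, `model` (trial-averaged TRF at
#'   the selected lambda), `predictions` (held-out channels x samples
#'   predictions at the selected lambda) and `actual` (demeaned EEG, same
#'   layout).
#' @export
crossval_lambda <- function(features, eeg, lambda = lambda_grid_decades(),
                            lag_min = 0, lag_max = 300, normalize = TRUE) {
  n <- length(features)
  if (n < 3L) abort_bad_arg("cross-validation needs at least 3 trials.")
  if (length(eeg) != n) abort_bad_arg("one EEG recording per trial required.")
  if (length(lambda) == 0L) abort_bad_arg("empty lambda grid.")
  lambda <- sort(unique(as.numeric(lambda)))
  fs <- eeg[[1]]$fs
  lags <- lag_samples(lag_min, lag_max, fs)
  ss <- lapply(seq_len(n), function(i) {
    trial_suffstats(features[[i]], eeg[[i]], lags, normalize)
  })
  st1 <- stack_features(features[[1]])
  chan <- eeg[[1]]$labels
  nchan <- length(chan)
  p <- ncol(ss[[1]]$x)

  score_rows <- vector("list", length(lambda))
  r_mean <- numeric(length(lambda))
  best <- list(r = -Inf)
  for (li in seq_along(lambda)) {
    lam <- lambda[li]
    w_all <- lapply(ss, ridge_weights_from_stats, lambda = lam)
    w_sum <- Reduce(`+`, w_all)
    r_mat <- matrix(NA_real_, n, nchan)
    preds <- vector("list", n)
    for (j in seq_len(n)) {
      w_avg <- (w_sum - w_all[[j]]) / (n - 1)
      pred <- ss[[j]]$x %*% w_avg
      r_mat[j, ] <- pearson_cols(pred, ss[[j]]$y)
      preds[[j]] <- t(pred)
    }
    r_mean[li] <- mean(r_mat, na.rm = TRUE)
    score_rows[[li]] <- tibble::tibble(
      lambda = lam,
      trial = rep(seq_len(n), times = nchan),
      channel = rep(chan, each = n),
      r = as.vector(r_mat)
    )
    if (r_mean[li] > best$r) {
      best <- list(
        r = r_mean[li], lambda = lam,
        w_mean = Reduce(`+`, w_all) / n,
        predictions = preds
      )
    }
  }
  nlag <- length(lags)
  npred <- nrow(st1$data)
  model <- new_trf_model(
    weights = array(best$w_mean, dim = c(nlag, npred, nchan)),
    lambda = best$lambda, lag_ms = c(lag_min, lag_max), fs = fs,
    tags = st1$tags, predictors = st1$names, channels = chan
  )
  structure(
    list(
      scores = dplyr::bind_rows(score_rows),
      lambda_summary = tibble::tibble(lambda = lambda, mean_r = r_mean),
      lambda = best$lambda,
      mean_r = best$r,
      model = model,
      predictions = best$predictions,
      actual = lapply(ss, function(s) t(s$y)),
      tags = st1$tags,
      channels = chan,
      n_trials = n
    ),
    class = "trf_cv"
  )
}

#' @export
print.trf_cv <- function(x, ...) {
  cat(sprintf(
    "<trf_cv [%s]>  %d trials, %d channels; lambda* = %g; mean r = %.4f\n",
    paste(x$tags, collapse = "+"), x$n_trials, length(x$channels),
    x$lambda, x$mean_r
  ))
  invisible(x)
}

#' Fit cross-validated encoding models for every subject of a study
#'
#' Tidy wrapper around [crossval_lambda()]: runs the leave-one-trial-out
#' procedure per subject and condition on the requested feature space(s)
#' and returns one row per fit.
#'
#' @param study a study tibble from [make_study()].
#' @param tags feature-space tag(s); several tags give one joint model.
#' @param conditions `"attended"`, `"unattended"` or both.
#' @param lambda ridge grid.
#' @param lag_min,lag_max lag window in ms.
#' @param channels channel-label subset for `mean_r` (default all).
#' @return A tibble with columns `subject`, `condition`, `tags`, `lambda`,
#'   `mean_r` and a `cv` list-column of `trf_cv` objects.
#' @export
fit_encoding_models <- function(study, tags = "s",
                                conditions = c("attended", "unattended"),
                                lambda = lambda_grid_decades(),
                                lag_min = 0, lag_max = 300,
                                channels = NULL) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  grid <- tidyr::expand_grid(
    subject = unique(study$subject),
    condition = conditions
  )
  res <- purrr::pmap(grid, function(subject, condition) {
    rows <- study[study$subject == subject, ]
    fcol <- if (condition == "attended") "features_att" else "features_unatt"
    feats <- lapply(rows[[fcol]], function(fl) unname(fl[tags]))
    cv <- crossval_lambda(feats, rows$eeg, lambda = lambda,
      lag_min = lag_min, lag_max = lag_max)
    mr <- cv$scores |>
      dplyr::filter(.data$lambda == cv$lambda) |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(r = mean(.data$r), .groups = "drop")
    tibble::tibble(
      subject = subject, condition = condition,
      tags = paste(tags, collapse = "+"),
      lambda = cv$lambda,
      mean_r = channel_mean_score(mr, channels),
      cv = list(cv)
    )
  })
  dplyr::bind_rows(res)
}
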