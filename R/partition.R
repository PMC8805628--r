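# Variance partitioning: per-feature-space cross-validated predictions,
# partial correlations controlling the other spaces' predictions, the
# residual-EEG confirmation path, joint-model comparisons, and the
# lag-windowed variant.

#' Cross-validated predictions for each feature space
#'
#' Fits one cross-validated encoding model per feature space, subject and
#' condition, and keeps the held-out EEG predictions at each subject's
#' optimal lambda. This is the input to [unique_contribution()].
#'
#' @param study a study tibble from [make_study()].
#' @param tags feature spaces to fit (default the four stimulus
#'   representations `s`, `sD`, `f`, `fo`).
#' @param conditions attended/unattended.
#' @param lambda ridge grid; the partial-correlation path defaults to the
#'   powers-of-two grid.
#' @param lag_min,lag_max lag window in ms.
#' @return A `space_predictions` tibble: `subject`, `condition`, `space`,
#'   `lambda`, `mean_r`, and a `cv` list-column.
#' @export
predictions_per_space <- function(study, tags = c("s", "sD", "f", "fo"),
                                  conditions = c("attended", "unattended"),
                                  lambda = lambda_grid_powers2(),
                                  lag_min = 0, lag_max = 300) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  out <- dplyr::bind_rows(lapply(tags, function(tg) {
    fits <- fit_encoding_models(study, tags = tg, conditions = conditions,
      lambda = lambda, lag_min = lag_min, lag_max = lag_max)
    fits$space <- tg
    fits
  }))
  out <- out[c("subject", "condition", "space", "lambda", "mean_r", "cv")]
  class(out) <- c("space_predictions", class(out))
  out
}

#' Partial correlation of two series controlling a set of series
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection onto the span of `z` plus an intercept. With empty `z` this
#' is the plain Pearson correlation.
#'
#' @param x,y numeric vectors of equal length.
#' @param z numeric matrix of control series (columns), or `NULL`.
#' @return Scalar partial correlation.
#' @export
partial_correlation <- function(x, y, z = NULL) {
  n <- length(x)
  if (length(y) != n) abort_bad_arg("`x` and `y` must have equal length.")
  if (is.null(z) || NCOL(z) == 0L) {
    return(stats::cor(x, y))
  }
  z <- as.matrix(z)
  if (nrow(z) != n) abort_bad_arg("`z` rows must match the series length.")
  if (n <= ncol(z) + 2L) abort_bad_arg("series too short for |z| controls.")
  qz <- qr(cbind(1, z))
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  if (stats::sd(ry) < 1e-12 * max(stats::sd(y), 1e-300)) {
    rlang::abort("`y` lies in the span of the controls (degenerate).",
      class = c("speechtrf_error_degenerate", "speechtrf_error"))
  }
  stats::cor(rx, ry)
}

# Concatenate a cv object's per-trial actual or predicted series for one
# channel index into a single vector.
concat_channel <- function(mats, ch) {
  unlist(lapply(mats, function(m) m[ch, ]), use.names = FALSE)
}

# Per-channel partial correlations for one subject/condition slice.
partial_by_channel <- function(actual, target_pred, control_preds) {
  nchan <- nrow(actual[[1]])
  vapply(seq_len(nchan), function(ch) {
    x <- concat_channel(actual, ch)
    y <- concat_channel(target_pred, ch)
    z <- if (length(control_preds) == 0L) NULL else
      vapply(control_preds, concat_channel, numeric(length(x)), ch = ch)
    partial_correlation(x, y, z)
  }, numeric(1))
}

pick_cv <- function(preds, subj, cond, space) {
  row <- preds$subject == subj & preds$condition == cond &
    preds$space == space
  if (sum(row) != 1L) {
    abort_bad_arg(sprintf("no unique fit for subject %s / %s / %s.",
      subj, cond, space))
  }
  preds$cv[[which(row)]]
}

#' Unique predictive power of one feature space
#'
#' For each subject and condition, computes the per-channel partial
#' correlation between the recorded EEG and the target space's
#' cross-validated prediction, controlling for the other spaces'
#' predictions (one control regressor per space, channel-matched), then
#' averages over the channel subset.
#'
#' @param preds a `space_predictions` tibble from [predictions_per_space()].
#' @param target feature-space tag whose unique contribution is wanted.
#' @param controls tags to partial out (default: all other spaces present).
#' @param channels channel-label subset for averaging (default all).
#' @return A tibble `subject`, `condition`, `feature_space`, `partial_r`;
#'   per-channel values are kept in the `by_channel` list-column.
#' @export
unique_contribution <- function(preds, target,
                                controls = NULL, channels = NULL) {
  stopifnot(inherits(preds, "space_predictions"))
  controls <- controls %||% setdiff(unique(preds$space), target)
  combos <- dplyr::distinct(preds[c("subject", "condition")])
  res <- purrr::pmap(combos, function(subject, condition) {
    cv_t <- pick_cv(preds, subject, condition, target)
    cv_c <- lapply(controls, pick_cv, preds = preds, subj = subject,
      cond = condition)
    r_ch <- partial_by_channel(
      cv_t$actual, cv_t$predictions,
      lapply(cv_c, function(cv) cv$predictions)
    )
    names(r_ch) <- cv_t$channels
    tibble::tibble(
      subject = subject, condition = condition, feature_space = target,
      partial_r = channel_mean_score(r_ch, channels),
      by_channel = list(r_ch)
    )
  })
  dplyr::bind_rows(res)
}

#' Residual-EEG confirmation of the unique contribution
#'
#' The second route to the same quantity: fit one joint cross-validated
#' model on the control spaces, subtract its held-out prediction from the
#' EEG, then model the residual EEG with the target space alone and report
#' its cross-validated prediction accuracy. The sign pattern and ordering
#' should agree with [unique_contribution()].
#'
#' @param study a study tibble.
#' @param target feature-space tag of interest.
#' @param controls tags of the joint control model.
#' @param conditions attended/unattended.
#' @param lambda ridge grid.
#' @param lag_min,lag_max lag window in ms.
#' @param channels channel subset for averaging.
#' @return A tibble `subject`, `condition`, `feature_space`, `residual_r`.
#' @export
residual_unique_contribution <- function(study, target,
                                         controls = c("s", "sD", "fo"),
                                         conditions = c("attended", "unattended"),
                                         lambda = lambda_grid_powers2(),
                                         lag_min = 0, lag_max = 300,
                                         channels = NULL) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  combos <- tidyr::expand_grid(
    subject = unique(study$subject), condition = conditions
  )
  res <- purrr::pmap(combos, function(subject, condition) {
    rows <- study[study$subject == subject, ]
    fcol <- if (condition == "attended") "features_att" else "features_unatt"
    feats_ctrl <- lapply(rows[[fcol]], function(fl) unname(fl[controls]))
    cv_ctrl <- crossval_lambda(feats_ctrl, rows$eeg, lambda = lambda,
      lag_min = lag_min, lag_max = lag_max)
    resid_eeg <- lapply(seq_len(nrow(rows)), function(i) {
      r <- cv_ctrl$actual[[i]] - cv_ctrl$predictions[[i]]
      eeg_recording(r, fs = rows$eeg[[i]]$fs, labels = rows$eeg[[i]]$labels)
    })
    feats_t <- lapply(rows[[fcol]], function(fl) fl[[target]])
    cv_t <- crossval_lambda(feats_t, resid_eeg, lambda = lambda,
      lag_min = lag_min, lag_max = lag_max)
    mr <- cv_t$scores |>
      dplyr::filter(.data$lambda == cv_t$lambda) |>
      dplyr::group_by(.data$channel) |>
      dplyr::summarise(r = mean(.data$r), .groups = "drop")
    tibble::tibble(
      subject = subject, condition = condition, feature_space = target,
      residual_r = channel_mean_score(mr, channels)
    )
  })
  dplyr::bind_rows(res)
}

#' Joint-model prediction accuracy
#'
#' Cross-validated prediction accuracy of single models whose design
#' matrices stack several feature spaces, e.g. the comparison set
#' `s`, `s+f`, `s+sD`, `s+fo`, `s+sD+f`, `s+fo+f`, `s+fo+sD`,
#' `s+fo+sD+f`.
#'
#' @param study a study tibble.
#' @param combos list of character vectors of tags, one per joint model.
#' @param conditions attended/unattended.
#' @param lambda ridge grid (model comparison defaults to decades).
#' @param lag_min,lag_max lag window in ms.
#' @param channels channel subset for averaging.
#' @return A tibble `subject`, `condition`, `model`, `lambda`, `mean_r`.
#' @export
joint_model_accuracy <- function(study, combos = joint_model_set(),
                                 conditions = c("attended", "unattended"),
                                 lambda = lambda_grid_decades(),
                                 lag_min = 0, lag_max = 300,
                                 channels = NULL) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  known <- c("s", "sD", "f", "fo", "vc")
  res <- lapply(combos, function(tags) {
    if (length(tags) == 0L) abort_bad_arg("empty tag combination.")
    if (!all(tags %in% known)) {
      abort_bad_arg(sprintf("unknown tag(s): %s",
        paste(setdiff(tags, known), collapse = ", ")))
    }
    fits <- fit_encoding_models(study, tags = tags, conditions = conditions,
      lambda = lambda, lag_min = lag_min, lag_max = lag_max,
      channels = channels)
    fits$model <- paste(tags, collapse = "+")
    fits[c("subject", "condition", "model", "lambda", "mean_r")]
  })
  dplyr::bind_rows(res)
}

#' @rdname joint_model_accuracy
#' @export
joint_model_set <- function() {
  list(
    "s",
    c("s", "f"), c("s", "sD"), c("s", "fo"),
    c("s", "sD", "f"), c("s", "fo", "f"), c("s", "fo", "sD"),
    c("s", "fo", "sD", "f")
  )
}

#' Lag-windowed unique contribution
#'
#' Repeats the unique-contribution procedure with the lag window restricted
#' to consecutive non-overlapping sub-windows (models for the target and
#' all controls are refit inside each window).
#'
#' @param study a study tibble.
#' @param target target feature-space tag.
#' @param controls control tags.
#' @param width_ms window width in ms; must divide the lag range.
#' @param lag_min,lag_max full lag range in ms.
#' @param conditions attended/unattended.
#' @param lambda ridge grid.
#' @param channels channel subset.
#' @return A tibble `subject`, `condition`, `feature_space`, `win_lo`,
#'   `win_hi`, `partial_r`.
#' @export
windowed_unique_contribution <- function(study, target = "f",
                                         controls = c("s", "sD", "fo"),
                                         width_ms = 50,
                                         lag_min = 0, lag_max = 300,
                                         conditions = c("attended", "unattended"),
                                         lambda = lambda_grid_powers2(),
                                         channels = NULL) {
  span <- lag_max - lag_min
  if (!is_whole(span / width_ms)) {
    abort_bad_arg("`width_ms` must divide the lag range exactly.")
  }
  los <- seq(lag_min, lag_max - width_ms, by = width_ms)
  fs <- study$eeg[[1]]$fs
  res <- lapply(los, function(lo) {
    # windows tile the lag range: a lag sample falling exactly on an
    # interior boundary belongs to the earlier window only
    lo_eff <- if (lo > lag_min && is_whole(lo * fs / 1000)) {
      (floor(lo * fs / 1000 + 1e-9) + 1) * 1000 / fs
    } else {
      lo
    }
    preds <- predictions_per_space(study, tags = c(target, controls),
      conditions = conditions, lambda = lambda,
      lag_min = lo_eff, lag_max = lo + width_ms)
    uc <- unique_contribution(preds, target, controls, channels)
    uc$win_lo <- lo
    uc$win_hi <- lo + width_ms
    uc[c("subject", "condition", "feature_space", "win_lo", "win_hi",
      "partial_r")]
  })
  dplyr::bind_rows(res)
}
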