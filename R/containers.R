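#' Stimulus feature set
#'
#' A multivariate stimulus time series at the EEG analysis rate: a numeric
#' matrix of predictors (rows) by samples (columns), its sampling rate, a
#' feature-space tag and predictor names. These are the regressors of the
#' forward encoding model.
#'
#' @param data numeric matrix, predictors x samples; must be finite.
#' @param fs sampling rate in Hz.
#' @param tag feature-space tag, one of `"s"` (mel spectrogram), `"sD"`
#'   (half-wave rectified spectrogram derivative), `"f"` (binary phonetic
#'   articulatory features), `"fo"` (phoneme onsets) or `"vc"`
#'   (vowel/consonant onsets).
#' @param names optional character vector of predictor names (one per row).
#'
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(data, fs, tag, names = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_bad_arg("`data` must be a numeric matrix (predictors x samples).")
  }
  if (anyNA(data) || any(!is.finite(data))) {
    abort_bad_arg("feature data must be finite (no NA/NaN/Inf).")
  }
  stopifnot_scalar_number(fs, "fs", min = 0, strict = TRUE)
  tag <- match.arg(tag, c("s", "sD", "f", "fo", "vc"))
  names <- names %||% rownames(data) %||%
    paste0(tag, seq_len(nrow(data)))
  if (length(names) != nrow(data)) {
    abort_bad_arg("`names` must have one entry per predictor row.")
  }
  rownames(data) <- names
  structure(
    list(data = data, fs = as.numeric(fs), tag = tag, names = names),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf(
    "<feature_set '%s'>  %d predictor(s) x %d samples @ %g Hz\n",
    x$tag, nrow(x$data), ncol(x$data), x$fs
  ))
  invisible(x)
}

#' @export
dim.feature_set <- function(x) dim(x$data)

n_samples <- function(x) ncol(x$data)

#' Multichannel EEG recording
#'
#' Channels x samples matrix with channel labels, unit-sphere 3-D electrode
#' positions, sampling rate, and (optionally) the indices of the two mastoid
#' reference channels. This is the response side of the encoding model.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels character vector of channel labels.
#' @param positions optional channels x 3 matrix of electrode positions;
#'   normalized internally to the unit sphere.
#' @param mastoids optional length-2 integer vector of mastoid channel
#'   indices (rows of `data`).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, labels = NULL, positions = NULL,
                          mastoids = NULL) {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort_bad_arg("`data` must be a numeric matrix (channels x samples).")
  }
  stopifnot_scalar_number(fs, "fs", min = 0, strict = TRUE)
  nc <- nrow(data)
  labels <- labels %||% rownames(data) %||% sprintf("CH%02d", seq_len(nc))
  if (length(labels) != nc) {
    abort_bad_arg("`labels` must have one entry per channel.")
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nc || ncol(positions) != 3L) {
      abort_bad_arg("`positions` must be a channels x 3 matrix.")
    }
    rad <- sqrt(rowSums(positions^2))
    if (any(rad == 0)) abort_bad_arg("electrode positions must be nonzero.")
    positions <- positions / rad
  }
  if (!is.null(mastoids)) {
    mastoids <- as.integer(mastoids)
    if (length(mastoids) != 2L || any(mastoids < 1L | mastoids > nc)) {
      abort_bad_arg("`mastoids` must index two channels of `data`.")
    }
  }
  rownames(data) <- labels
  structure(
    list(
      data = data, fs = as.numeric(fs), labels = labels,
      positions = positions, mastoids = mastoids
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording>  %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    if (is.null(x$mastoids)) "" else
      sprintf("; mastoids: %s", paste(x$labels[x$mastoids], collapse = ", "))
  ))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# Stack several feature sets (same fs and sample count) into one block for
# joint-model designs. Returns a plain list understood by lag_matrix().
stack_features <- function(fsets) {
  if (inherits(fsets, "feature_set")) fsets <- list(fsets)
  stopifnot(length(fsets) >= 1L)
  fs <- unique(vapply(fsets, function(f) f$fs, numeric(1)))
  ns <- unique(vapply(fsets, function(f) ncol(f$data), integer(1)))
  if (length(fs) != 1L || length(ns) != 1L) {
    abort_bad_arg("feature sets must share sampling rate and length to be stacked.")
  }
  tags <- vapply(fsets, function(f) f$tag, character(1))
  list(
    data = do.call(rbind, lapply(fsets, function(f) f$data)),
    fs = fs,
    tags = tags,
    names = unlist(lapply(fsets, function(f) paste(f$tag, f$names, sep = ":"))),
    blocks = rep(tags, vapply(fsets, function(f) nrow(f$data), integer(1)))
  )
}
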