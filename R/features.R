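# speech representations: mel spectrogram (s), half-wave rectified
# derivative (sD), phonetic features (f), phoneme onsets (fo) and the
# vowel/consonant control (vc), all on the EEG analysis time base.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank (unit peak), n_bands x (n_fft/2 + 1).
mel_filterbank <- function(n_bands, n_fft, sr, fmin = 64, fmax = NULL) {
  fmax <- fmax %||% min(sr / 2, 8000)
  edges <- mel_to_hz(seq(hz_to_mel(fmin), hz_to_mel(fmax),
    length.out = n_bands + 2L))
  freqs <- seq(0, sr / 2, length.out = n_fft %/% 2L + 1L)
  fb <- matrix(0, n_bands, length(freqs))
  for (b in seq_len(n_bands)) {
    lo <- edges[b]; ctr <- edges[b + 1L]; hi <- edges[b + 2L]
    up <- (freqs - lo) / (ctr - lo)
    down <- (hi - freqs) / (hi - ctr)
    fb[b, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "centers_hz") <- edges[2:(n_bands + 1L)]
  fb
}

#' Log-compressed mel spectrogram of an audio waveform
#'
#' Decomposes the stimulus energy into mel-spaced frequency bands with a
#' logarithmic compressive nonlinearity, sampled at the EEG analysis rate.
#' Frames of `frame_ms` are taken centred at the output sample times (Hann
#' window), so no audio-rate resampling is needed; band energies are the
#' mel-filtered power spectrum and compression is `log(x + eps)` with
#' `eps = 1e-6 * max(energy)`.
#'
#' @param audio numeric vector (mono waveform) or the list returned by
#'   [read_wav()].
#' @param sr audio sampling rate in Hz (ignored if `audio` carries its own).
#' @param n_bands number of mel bands (default 31).
#' @param out_rate output (analysis) sampling rate in Hz, default 128.
#' @param frame_ms analysis frame length in milliseconds.
#'
#' @return A [feature_set()] with tag `"s"`, `n_bands` rows.
#' @export
mel_spectrogram <- function(audio, sr = NULL, n_bands = 31, out_rate = 128,
                            frame_ms = 25) {
  if (is.list(audio)) {
    sr <- sr %||% audio$fs
    audio <- audio$samples
  }
  if (is.matrix(audio)) audio <- colMeans(audio) # downmix to mono
  stopifnot_scalar_number(sr, "sr", min = 0, strict = TRUE)
  if (out_rate > sr) abort_bad_arg("`out_rate` must not exceed the audio rate.")
  if (anyNA(audio) || any(!is.finite(audio))) {
    abort_bad_arg("audio must be finite.")
  }
  flen <- round(frame_ms / 1000 * sr)
  if (length(audio) < flen) {
    abort_bad_arg("audio is shorter than one analysis frame.")
  }
  n_out <- floor(length(audio) / sr * out_rate)
  n_fft <- 2^ceiling(log2(flen))
  fb <- mel_filterbank(n_bands, n_fft, sr)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(flen) / (flen + 1)) # Hann
  centers <- round((seq_len(n_out) - 0.5) / out_rate * sr)
  half <- flen %/% 2L
  pad <- c(numeric(half), audio, numeric(flen))
  pw <- matrix(0, n_fft %/% 2L + 1L, n_out)
  for (k in seq_len(n_out)) {
    fr <- pad[centers[k] + seq_len(flen)] * win
    sp <- stats::fft(c(fr, numeric(n_fft - flen)))
    pw[, k] <- Mod(sp[seq_len(n_fft %/% 2L + 1L)])^2
  }
  energy <- fb %*% pw
  eps <- 1e-6 * max(energy, .Machine$double.eps)
  s <- log(energy + eps)
  feature_set(s, fs = out_rate, tag = "s",
    names = sprintf("mel%02d", seq_len(n_bands)))
}

#' Half-wave rectified temporal derivative of a spectrogram
#'
#' Computes the first difference of each spectrogram band over time and
#' keeps only the positive part, an approximation of acoustic onsets. The
#' first column is zero so the output keeps the input's shape.
#'
#' @param s a [feature_set()] with tag `"s"`.
#' @return A [feature_set()] with tag `"sD"`.
#' @export
half_wave_derivative <- function(s) {
  stopifnot(inherits(s, "feature_set"))
  if (s$tag != "s") {
    abort_bad_arg("`half_wave_derivative()` expects a spectrogram (tag 's').")
  }
  d <- cbind(0, pmax(s$data[, -1L, drop = FALSE] -
    s$data[, -ncol(s$data), drop = FALSE], 0))
  feature_set(d, fs = s$fs, tag = "sD", names = s$names)
}

#' Phonetic feature, phoneme-onset and vowel/consonant time series
#'
#' Converts a phoneme alignment into impulse-train predictors at the
#' analysis rate. In `"full"` mode each phoneme contributes a unit impulse
#' at its onset sample in every row whose articulatory feature is active
#' for that phoneme (a binary features x samples matrix); `"onsets"`
#' collapses this to a single row marking every phoneme onset; `"vc"` keeps
#' two rows, one marking vowel onsets and one consonant onsets. Onset
#' impulses (rather than sustained codes) are used throughout; set
#' `sustain = TRUE` for a duration-coded variant.
#'
#' @param alignment data frame with columns `phoneme`, `onset`, `offset`
#'   (seconds), e.g. from [read_alignment()].
#' @param inventory a [phoneme_inventory()].
#' @param out_rate analysis sampling rate in Hz.
#' @param duration total duration in seconds (sets the number of samples).
#' @param mode `"full"`, `"onsets"` or `"vc"`.
#' @param sustain if `TRUE`, mark every sample the phoneme spans instead of
#'   only its onset sample.
#'
#' @return A [feature_set()] with tag `"f"`, `"fo"` or `"vc"`.
#' @export
phonetic_features <- function(alignment, inventory = phoneme_inventory(),
                              out_rate = 128, duration,
                              mode = c("full", "onsets", "vc"),
                              sustain = FALSE) {
  mode <- match.arg(mode)
  stopifnot_scalar_number(duration, "duration", min = 0, strict = TRUE)
  alignment <- as.data.frame(alignment)
  if (nrow(alignment) > 0 && any(alignment$onset >= duration)) {
    abort_bad_arg("alignment onsets must lie before `duration`.")
  }
  fmat <- feature_matrix(inventory)
  unknown <- setdiff(unique(alignment$phoneme), rownames(fmat))
  if (length(unknown) > 0) {
    rlang::abort(
      sprintf("phoneme label(s) not in inventory: %s",
        paste(unknown, collapse = ", ")),
      class = c("speechtrf_error_unknown_phoneme", "speechtrf_error"),
      phonemes = unknown
    )
  }
  n_t <- floor(duration * out_rate)
  samp_of <- function(t) pmin(pmax(round(t * out_rate), 0) + 1L, n_t)
  rows <- switch(mode,
    full = t(fmat[alignment$phoneme, , drop = FALSE]),
    onsets = matrix(1, 1L, nrow(alignment)),
    vc = {
      cls <- inventory$class[match(alignment$phoneme, inventory$phoneme)]
      rbind(vowel = as.numeric(cls == "vowel"),
            consonant = as.numeric(cls == "consonant"))
    }
  )
  npred <- nrow(rows)
  out <- matrix(0, npred, n_t)
  if (nrow(alignment) > 0) {
    on <- samp_of(alignment$onset)
    if (sustain) {
      off <- samp_of(pmin(alignment$offset, duration - 1 / out_rate))
      for (k in seq_len(nrow(alignment))) {
        span <- on[k]:off[k]
        out[, span] <- pmax(out[, span, drop = FALSE], rows[, k])
      }
    } else {
      for (k in seq_len(nrow(alignment))) {
        out[, on[k]] <- pmax(out[, on[k]], rows[, k])
      }
    }
  }
  nm <- switch(mode,
    full = colnames(fmat),
    onsets = "onset",
    vc = c("vowel", "consonant")
  )
  feature_set(out, fs = out_rate,
    tag = switch(mode, full = "f", onsets = "fo", vc = "vc"), names = nm)
}

#' Z-score the predictors of a feature set
#'
#' Each predictor row is centred and scaled to unit standard deviation,
#' either with its own statistics or with externally supplied ones (e.g.
#' training-fold statistics applied to a held-out trial). Constant rows map
#' to all zeros rather than erroring.
#'
#' @param fs a [feature_set()].
#' @param stats optional list with numeric vectors `mean` and `sd` (one
#'   entry per predictor) to use instead of the set's own statistics.
#'
#' @return A [feature_set()] with the same shape; the statistics used are
#'   attached as attribute `"stats"`.
#' @export
normalize_features <- function(fs, stats = NULL) {
  stopifnot(inherits(fs, "feature_set"))
  ctr <- stats$mean %||% rowMeans(fs$data)
  scl <- stats$sd %||% apply(fs$data, 1L, stats::sd)
  out <- feature_set(zscore_rows(fs$data, ctr, scl), fs = fs$fs,
    tag = fs$tag, names = fs$names)
  attr(out, "stats") <- list(mean = ctr, sd = scl)
  out
}
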