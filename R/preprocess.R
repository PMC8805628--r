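# EEG preprocessing chain: mastoid re-reference -> bad-channel detection
# and spherical-spline interpolation -> polyphase downsampling to the
# analysis rate -> zero-phase Kaiser-window FIR band-pass (0.2-8 Hz).

#' Re-reference EEG to the mastoid average
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#'
#' @param eeg an [eeg_recording()] with `mastoids` set.
#' @return The re-referenced [eeg_recording()].
#' @export
rereference_mastoids <- function(eeg) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (is.null(eeg$mastoids)) {
    abort_bad_arg("recording has no mastoid channel indices.")
  }
  ref <- colMeans(eeg$data[eeg$mastoids, , drop = FALSE])
  eeg$data <- sweep(eeg$data, 2L, ref)
  eeg
}

#' Detect bad channels by the standard-deviation ratio rule
#'
#' A channel is flagged when its standard deviation is below one third of,
#' or above three times, the mean standard deviation over all channels
#' (itself included).
#'
#' @param eeg an [eeg_recording()] (at least 2 channels).
#' @param exclude channel indices ignored by the rule (e.g. mastoids);
#'   defaults to the recording's mastoids.
#' @return Integer vector of bad channel indices (possibly empty).
#' @export
detect_bad_channels <- function(eeg, exclude = eeg$mastoids) {
  stopifnot(inherits(eeg, "eeg_recording"))
  scalp <- setdiff(seq_len(nrow(eeg$data)), exclude)
  if (length(scalp) < 2L) abort_bad_arg("need at least 2 channels.")
  sds <- apply(eeg$data[scalp, , drop = FALSE], 1L, stats::sd)
  m <- mean(sds)
  scalp[sds < m / 3 | sds > 3 * m]
}

# Perrin-style spherical spline basis function g(cos(angle)), stiffness m,
# truncated Legendre series.
spline_g <- function(x, m = 4, nterms = 50) {
  # Legendre polynomials P_n(x) by recurrence, n = 1..nterms
  p_prev <- rep(1, length(x)) # P_0
  p_cur <- x # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:nterms) {
    p_new <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p_cur
    p_cur <- p_new
  }
  acc / (4 * pi)
}

# Interpolation weights for one bad electrode: with the constrained system
# A = [[G, 1], [1', 0]] and interpolant [g(bad,goods), 1] %*% solve(A, [z; 0]),
# the weights on the neighbor signals z are the first k entries of
# t(solve(A)) %*% [gvec, 1]; they sum to 1 by the constraint row.
spline_weights_exact <- function(bad_pos, good_pos, m = 4, nterms = 50) {
  k <- nrow(good_pos)
  cos_gg <- pmin(pmax(tcrossprod(good_pos), -1), 1)
  a <- rbind(cbind(spline_g(cos_gg, m, nterms), 1), c(rep(1, k), 0))
  cos_bg <- as.vector(pmin(pmax(good_pos %*% bad_pos, -1), 1))
  gvec <- c(spline_g(cos_bg, m, nterms), 1)
  (solve(t(a)) %*% gvec)[seq_len(k)]
}

#' Interpolate bad channels by spherical splines
#'
#' Each flagged channel is replaced by a spherical-spline estimate fitted
#' on its four nearest good neighbors (great-circle distance on the unit
#' sphere, ties broken by channel index). The interpolation weights sum to
#' one, so a constant field is reproduced exactly.
#'
#' @param eeg an [eeg_recording()] with electrode `positions`.
#' @param bad integer vector of bad channel indices, e.g. from
#'   [detect_bad_channels()].
#' @param n_neighbors number of good neighbors used (default 4).
#' @return The [eeg_recording()] with bad channels replaced.
#' @export
interpolate_channels <- function(eeg, bad, n_neighbors = 4) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (length(bad) == 0L) return(eeg)
  if (is.null(eeg$positions)) abort_bad_arg("electrode positions required.")
  good <- setdiff(seq_len(nrow(eeg$data)), c(bad, eeg$mastoids))
  if (length(good) < n_neighbors) {
    abort_bad_arg(sprintf("need at least %d good channels.", n_neighbors))
  }
  for (b in bad) {
    ang <- acos(pmin(pmax(eeg$positions[good, , drop = FALSE] %*%
      eeg$positions[b, ], -1), 1))
    nb <- good[order(ang, good)[seq_len(n_neighbors)]]
    w <- spline_weights_exact(eeg$positions[b, ],
      eeg$positions[nb, , drop = FALSE])
    eeg$data[b, ] <- as.vector(crossprod(w, eeg$data[nb, , drop = FALSE]))
  }
  eeg
}

# Rational-ratio resampling of one vector: zero-stuff by p, zero-phase
# Kaiser FIR low-pass at the tighter of the two Nyquist edges (gain p),
# keep every q-th sample.
resample_vec <- function(x, p, q, taps_per_branch = 20, atten_db = 60) {
  if (p == 1 && q == 1) return(x)
  up <- if (p > 1) {
    u <- numeric(length(x) * p)
    u[seq(1, by = p, length.out = length(x))] <- x
    u
  } else {
    x
  }
  n <- taps_per_branch * max(p, q)
  n <- n + n %% 2L
  b <- p * signal::fir1(n, 1 / max(p, q),
    window = signal::kaiser(n + 1L, kaiser_beta(atten_db)))
  y <- fir_zerophase(up, b)
  y[seq(1, length(y), by = q)]
}

#' Resample EEG to the analysis rate
#'
#' Anti-aliased polyphase resampling of every channel to `out_rate`
#' (zero-phase Kaiser-window FIR low-pass at the target Nyquist edge).
#'
#' @param eeg an [eeg_recording()].
#' @param out_rate target rate in Hz; must not exceed the current rate.
#' @return The resampled [eeg_recording()].
#' @export
eeg_resample <- function(eeg, out_rate = 128) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (out_rate > eeg$fs) {
    abort_bad_arg("`out_rate` must not exceed the current sampling rate.")
  }
  if (out_rate == eeg$fs) return(eeg)
  g <- pracma_gcd(round(out_rate * 1e6), round(eeg$fs * 1e6))
  p <- round(out_rate * 1e6) / g
  q <- round(eeg$fs * 1e6) / g
  n_out <- ceiling(ncol(eeg$data) * p / q)
  out <- matrix(0, nrow(eeg$data), n_out)
  for (c in seq_len(nrow(eeg$data))) {
    y <- resample_vec(eeg$data[c, ], p, q)
    out[c, ] <- y[seq_len(n_out)]
  }
  eeg_recording(out, fs = out_rate, labels = eeg$labels,
    positions = eeg$positions, mastoids = eeg$mastoids)
}

pracma_gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

# Kaiser beta for a target stopband attenuation (dB), Kaiser's formula.
kaiser_beta <- function(atten_db = 60) {
  if (atten_db > 50) 0.1102 * (atten_db - 8.7)
  else if (atten_db >= 21) 0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  else 0
}

# Zero-phase single-pass FIR: symmetric (linear-phase) kernel applied by
# convolution with exact group-delay compensation.
fir_zerophase <- function(x, b) {
  n <- length(b)
  gd <- (n - 1L) %/% 2L
  y <- signal::fftfilt(b, c(x, numeric(n)))
  y[(gd + 1L):(gd + length(x))]
}

#' Zero-phase Kaiser-window FIR band-pass filter
#'
#' High-pass and low-pass Kaiser-window FIR filters applied in sequence,
#' each as a single-pass linear-phase filter with exact group-delay
#' compensation (zero net phase shift). Default orders are scaled to the
#' recording's sampling rate from reference orders of 20,000 (high-pass)
#' and 1,000 (low-pass) taps at 512 Hz; the Kaiser beta targets 60 dB
#' stopband attenuation.
#'
#' @param eeg an [eeg_recording()].
#' @param lo high-pass edge in Hz (default 0.2).
#' @param hi low-pass edge in Hz (default 8); requires `fs > 2 * hi`.
#' @param hp_order,lp_order filter orders (taps - 1); defaults scale with
#'   the sampling rate as described above.
#' @param atten_db stopband attenuation target in dB.
#' @return The filtered [eeg_recording()].
#' @export
bandpass_fir <- function(eeg, lo = 0.2, hi = 8,
                         hp_order = NULL, lp_order = NULL, atten_db = 60) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (eeg$fs <= 2 * hi) {
    abort_bad_arg("sampling rate must exceed twice the low-pass edge.")
  }
  hp_order <- hp_order %||% round(20000 * eeg$fs / 512)
  lp_order <- lp_order %||% round(1000 * eeg$fs / 512)
  hp_order <- hp_order + hp_order %% 2L # even order, type-I linear phase
  lp_order <- lp_order + lp_order %% 2L
  n_t <- ncol(eeg$data)
  if (n_t <= max(hp_order, lp_order)) {
    abort_bad_arg("trial is shorter than the filter order.")
  }
  beta <- kaiser_beta(atten_db)
  nyq <- eeg$fs / 2
  bh <- signal::fir1(hp_order, lo / nyq, type = "high",
    window = signal::kaiser(hp_order + 1L, beta))
  bl <- signal::fir1(lp_order, hi / nyq, type = "low",
    window = signal::kaiser(lp_order + 1L, beta))
  for (c in seq_len(nrow(eeg$data))) {
    eeg$data[c, ] <- fir_zerophase(fir_zerophase(eeg$data[c, ], bh), bl)
  }
  eeg
}

#' Full preprocessing chain
#'
#' Applies, in order: mastoid re-reference, bad-channel detection and
#' spherical-spline interpolation, downsampling to `out_rate`, and the
#' 0.2-8 Hz zero-phase FIR band-pass. Bad channels are detected on the
#' broadband signal before resampling and filtering.
#'
#' @param eeg an [eeg_recording()].
#' @param out_rate analysis rate in Hz.
#' @param lo,hi band edges in Hz.
#' @param drop_mastoids drop the mastoid channels after re-referencing.
#' @return A preprocessed [eeg_recording()] at `out_rate`.
#' @export
preprocess_eeg <- function(eeg, out_rate = 128, lo = 0.2, hi = 8,
                           drop_mastoids = TRUE) {
  if (!is.null(eeg$mastoids)) eeg <- rereference_mastoids(eeg)
  bad <- detect_bad_channels(eeg)
  if (length(bad) > 0L) eeg <- interpolate_channels(eeg, bad)
  if (drop_mastoids && !is.null(eeg$mastoids)) {
    keep <- setdiff(seq_len(nrow(eeg$data)), eeg$mastoids)
    eeg <- eeg_recording(eeg$data[keep, , drop = FALSE], fs = eeg$fs,
      labels = eeg$labels[keep],
      positions = if (is.null(eeg$positions)) NULL else
        eeg$positions[keep, , drop = FALSE])
  }
  eeg <- eeg_resample(eeg, out_rate)
  bandpass_fir(eeg, lo = lo, hi = hi)
}
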