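# Synthetic two-talker study generator. Produces phoneme alignments,
# acoustic/phonetic feature streams with controllable acoustic-phonetic
# coupling, and EEG built as lag-limited convolution of attended (and
# attenuated unattended) features with known smooth kernels plus
# spatially correlated 1/f noise — so every downstream stage has a
# parameter-recovery test with known ground truth.

#' Simulation configuration
#'
#' Bundles the study-level parameters of the synthetic two-talker
#' experiment. Defaults are the desk-scale study: 12 subjects, 20 trials
#' of 30 s at 128 Hz with 32 channels, phoneme rate 12/s, acoustic-
#' phonetic coupling 0.5, pink (1/f) noise at 0 dB SNR.
#'
#' @param n_subjects,n_trials,duration number of subjects, trials per
#'   subject, and trial duration in seconds.
#' @param fs analysis sampling rate in Hz.
#' @param n_channels EEG channel count.
#' @param n_bands mel bands of the synthetic spectrogram.
#' @param phoneme_rate mean phoneme rate per second.
#' @param coupling acoustic-phonetic coupling coefficient in [0, 1]: 1
#'   makes the spectrogram fully determined by phoneme identity, 0 makes
#'   it independent of the phoneme stream.
#' @param noise_alpha spectral exponent of the 1/f^alpha channel noise.
#' @param noise_sd fixed noise standard deviation (microvolts); `NULL`
#'   derives the noise scale from `snr_db`.
#' @param snr_db signal-to-noise ratio in dB used when `noise_sd` is
#'   `NULL` (default 0 dB: equal signal and noise power).
#' @param lag_max upper edge of the kernel/analysis lag window in ms.
#' @param seed integer seed; the seed fully determines the study.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 12, n_trials = 20, duration = 30,
                       fs = 128, n_channels = 32, n_bands = 31,
                       phoneme_rate = 12, coupling = 0.5,
                       noise_alpha = 1, noise_sd = NULL, snr_db = 0,
                       lag_max = 300, seed = 1) {
  for (nm in c("n_subjects", "n_trials", "fs", "n_channels",
    "n_bands", "lag_max")) {
    stopifnot_scalar_number(get(nm), nm, min = 1)
  }
  stopifnot_scalar_number(duration, "duration", min = 0, strict = TRUE)
  stopifnot_scalar_number(phoneme_rate, "phoneme_rate", min = 0)
  if (coupling < 0 || coupling > 1) {
    abort_bad_arg("`coupling` must lie in [0, 1].",
      class = "speechtrf_error_config")
  }
  if (!is_whole(duration * fs)) {
    abort_bad_arg("`duration * fs` must be a whole number of samples.",
      class = "speechtrf_error_config")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
      duration = duration, fs = fs, n_channels = as.integer(n_channels),
      n_bands = as.integer(n_bands), phoneme_rate = phoneme_rate,
      coupling = coupling, noise_alpha = noise_alpha, noise_sd = noise_sd,
      snr_db = snr_db, lag_max = lag_max, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Electrode layout: Fibonacci lattice on the upper unit hemisphere.
synthetic_positions <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - k / n            # upper hemisphere only
  phi <- pi * (1 + sqrt(5)) * k
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# 1/f^alpha Gaussian noise, unit SD, via spectral shaping.
pink_noise <- function(n_t, alpha = 1) {
  w <- stats::fft(stats::rnorm(n_t))
  k <- seq_len(n_t) - 1L
  f <- pmin(k, n_t - k) # symmetric frequency index, DC at 0
  scale <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::fft(w * scale, inverse = TRUE)) / n_t
  x / stats::sd(x)
}

# Smooth spatial mixing matrix from electrode geometry plus a random
# component; rows scaled so mixed channels keep unit SD approximately.
spatial_mixing <- function(positions, width = 0.8) {
  ang <- acos(pmin(pmax(tcrossprod(positions), -1), 1))
  k <- exp(-ang^2 / (2 * width^2))
  k <- k + 0.05 * matrix(stats::rnorm(length(k)), nrow(k))
  k / sqrt(rowSums(k^2))
}

# Per-phoneme spectral templates: smooth-in-frequency random patterns,
# fixed for a study so every utterance of a phoneme shares its template.
phoneme_templates <- function(n_bands, inventory) {
  nph <- nrow(inventory)
  raw <- matrix(stats::rnorm(n_bands * nph), n_bands, nph)
  # smooth across bands (Gaussian kernel, sigma = 2 bands)
  idx <- seq_len(n_bands)
  g <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * 2^2)))
  g <- g / rowSums(g)
  sm <- g %*% raw
  sm <- sweep(sm, 2L, sqrt(colMeans(sm^2)), "/")
  colnames(sm) <- inventory$phoneme
  sm
}

#' Generate a random phoneme alignment
#'
#' Renewal sequence of phonemes with log-normal durations around
#' `1/rate`, clipped to [30, 300] ms, labels drawn uniformly from the
#' inventory. Phonemes are contiguous (each offset equals the next
#' onset); the last offset is truncated to `duration`. `rate = 0` is the
#' degenerate single-phoneme case.
#'
#' @param duration total duration in seconds (> 0).
#' @param rate mean phoneme rate per second (>= 0).
#' @param inventory a [phoneme_inventory()].
#' @param seed optional RNG seed; the same seed reproduces the alignment
#'   exactly.
#' @param force_label phoneme label used in the degenerate `rate = 0` case.
#' @return A tibble `phoneme`, `onset`, `offset` (seconds).
#' @export
generate_phoneme_sequence <- function(duration, rate,
                                      inventory = phoneme_inventory(),
                                      seed = NULL, force_label = NULL) {
  stopifnot_scalar_number(duration, "duration", min = 0, strict = TRUE)
  stopifnot_scalar_number(rate, "rate", min = 0)
  if (nrow(inventory) == 0L) {
    abort_bad_arg("empty phoneme inventory.", class = "speechtrf_error_config")
  }
  if (rate == 0) {
    lab <- force_label %||% inventory$phoneme[1]
    return(tibble::tibble(
      phoneme = lab, onset = 0, offset = min(0.3, duration)
    ))
  }
  with_seed_maybe(seed, {
    sdlog <- 0.4
    meanlog <- log(1 / rate) - sdlog^2 / 2
    n_guess <- ceiling(duration * rate * 1.6) + 8L
    repeat {
      durs <- pmin(pmax(stats::rlnorm(n_guess, meanlog, sdlog), 0.03), 0.3)
      if (sum(durs) >= duration) break
      n_guess <- n_guess * 2L
    }
    offs <- cumsum(durs)
    keep <- c(TRUE, offs[-length(offs)] < duration)
    durs <- durs[keep]
    offs <- pmin(offs[keep], duration)
    ons <- c(0, offs[-length(offs)])
    labs <- sample(inventory$phoneme, length(durs), replace = TRUE)
    tibble::tibble(phoneme = labs, onset = ons, offset = offs)
  })
}

#' Generate the full feature bundle of one synthetic stream
#'
#' Builds all five feature spaces for one talker's stream: the synthetic
#' spectrogram `s` mixes per-phoneme spectral templates (weighted by the
#' coupling coefficient) with smooth 1/f band noise, so acoustics are
#' correlated with — but not identical to — the phonetic features; `sD`,
#' `f`, `fo` and `vc` are then derived exactly as from real audio.
#'
#' @param alignment tibble `phoneme`, `onset`, `offset`.
#' @param config a [sim_config()].
#' @param inventory a [phoneme_inventory()].
#' @param templates optional band x phoneme template matrix (shared
#'   across the study); generated from the ambient RNG stream if `NULL`.
#' @param seed optional RNG seed.
#' @return Named list of [feature_set()]s: `s`, `sD`, `f`, `fo`, `vc`.
#' @export
generate_feature_bundle <- function(alignment, config,
                                    inventory = phoneme_inventory(),
                                    templates = NULL, seed = NULL) {
  with_seed_maybe(seed, {
    templates <- templates %||% phoneme_templates(config$n_bands, inventory)
    n_t <- round(config$duration * config$fs)
    nb <- config$n_bands
    a <- matrix(0, nb, n_t)
    for (k in seq_len(nrow(alignment))) {
      i0 <- min(round(alignment$onset[k] * config$fs) + 1L, n_t)
      i1 <- min(max(round(alignment$offset[k] * config$fs), i0), n_t)
      span <- i0:i1
      env <- 0.5 - 0.5 * cos(2 * pi * seq_along(span) / (length(span) + 1))
      a[, span] <- a[, span] +
        templates[, alignment$phoneme[k]] %o% env
    }
    b <- t(vapply(seq_len(nb), function(i) pink_noise(n_t, 1),
      numeric(n_t)))
    std <- function(m) zscore_rows(m)
    sdat <- config$coupling * std(a) + (1 - config$coupling) * std(b)
    s <- feature_set(sdat, fs = config$fs, tag = "s",
      names = sprintf("mel%02d", seq_len(nb)))
    list(
      s = s,
      sD = half_wave_derivative(s),
      f = phonetic_features(alignment, inventory, config$fs,
        config$duration, mode = "full"),
      fo = phonetic_features(alignment, inventory, config$fs,
        config$duration, mode = "onsets"),
      vc = phonetic_features(alignment, inventory, config$fs,
        config$duration, mode = "vc")
    )
  })
}

#' Ground-truth TRF kernels with per-stream attention gains
#'
#' Generates smooth random kernels (Gabor-like temporal bumps with
#' spatially smooth channel loadings) for the requested feature spaces,
#' with kernel support confined to `support_ms` inside the analysis lag
#' window, and a pair of nonnegative gains (attended, unattended) per
#' space. The default configuration drives the EEG with an acoustic
#' kernel applied equally to both streams and a phonetic-feature kernel
#' applied to the attended stream only. When a `calibration` feature
#' bundle is supplied, each space's kernel is rescaled so its convolved
#' component has unit RMS on that bundle, making gains comparable across
#' spaces.
#'
#' @param config a [sim_config()].
#' @param gains named list of `c(attended, unattended)` gain pairs; the
#'   names select which feature spaces drive the EEG.
#' @param support_ms kernel support window in ms (inside `[0, lag_max]`):
#'   either one `c(lo, hi)` vector for all spaces or a named list with one
#'   window per space (e.g. to confine the phonetic kernel to a single lag
#'   window while the acoustic kernel stays broad).
#' @param inventory a [phoneme_inventory()] (sets the `f` dimension).
#' @param calibration optional feature bundle used to equalize component
#'   scale across spaces.
#' @param seed optional RNG seed.
#' @return A `gt_kernels` list: per space, `weights` (lags x predictors x
#'   channels), `gain_att`, `gain_unatt`, `support_ms`.
#' @export
ground_truth_kernels <- function(config,
                                 gains = list(s = c(1, 1), f = c(1, 0)),
                                 support_ms = c(30, 280),
                                 inventory = phoneme_inventory(),
                                 calibration = NULL, seed = NULL) {
  if (any(unlist(gains) < 0)) abort_bad_arg("gains must be >= 0.")
  if (!is.list(support_ms)) {
    support_ms <- stats::setNames(
      rep(list(support_ms), length(gains)), names(gains))
  }
  for (sp in names(gains)) {
    sup <- support_ms[[sp]]
    if (is.null(sup) || sup[1] < 0 || sup[2] > config$lag_max) {
      abort_bad_arg("kernel support must lie inside the analysis lag window.")
    }
  }
  with_seed_maybe(seed, {
    lags <- lag_samples(0, config$lag_max, config$fs)
    lag_ms <- lags / config$fs * 1000
    nchan <- config$n_channels
    mix <- spatial_mixing(synthetic_positions(nchan))
    npred_of <- c(s = config$n_bands, sD = config$n_bands,
      f = n_features(inventory), fo = 1, vc = 2)
    out <- list()
    for (space in names(gains)) {
      npred <- npred_of[[space]]
      sup <- support_ms[[space]]
      w <- array(0, dim = c(length(lags), npred, nchan))
      inside <- lag_ms >= sup[1] & lag_ms <= sup[2]
      pad <- min(20, (sup[2] - sup[1]) / 4)
      for (p in seq_len(npred)) {
        ctr <- stats::runif(1, sup[1] + pad, sup[2] - pad)
        sigma <- stats::runif(1, 20, 45)
        freq <- stats::runif(1, 2, 5)
        phase <- stats::runif(1, 0, 2 * pi)
        prof <- exp(-(lag_ms - ctr)^2 / (2 * sigma^2)) *
          cos(2 * pi * freq * (lag_ms - ctr) / 1000 + phase)
        prof[!inside] <- 0
        load <- as.vector(mix %*% stats::rnorm(nchan))
        load <- load / sqrt(mean(load^2))
        w[, p, ] <- prof %o% load
      }
      if (!is.null(calibration)) {
        comp <- convolve_kernel(calibration[[space]], w, lags)
        rms <- sqrt(mean(comp^2))
        if (rms > 0) w <- w / rms
      }
      out[[space]] <- list(
        weights = w,
        gain_att = gains[[space]][1], gain_unatt = gains[[space]][2],
        support_ms = sup
      )
    }
    structure(out, class = "gt_kernels", lags = lags, fs = config$fs)
  })
}

# Convolve one feature set with a kernel array over the shared lag grid;
# returns channels x samples.
convolve_kernel <- function(features, w, lags) {
  d <- dim(w)
  s <- lag_design(features$data, lags)
  t(s %*% matrix(w, nrow = d[1] * d[2]))
}

#' Simulate one trial's EEG from feature streams and ground-truth kernels
#'
#' The EEG is the sum over feature spaces of the attended stream's
#' features convolved with the space's kernel times the attended gain,
#' plus the unattended stream's convolution times the unattended gain,
#' plus spatially correlated 1/f^alpha Gaussian noise. The noise scale is
#' `config$noise_sd` when set, otherwise derived from `config$snr_db`
#' relative to the summed signal power.
#'
#' @param features_att,features_unatt named feature bundles (as from
#'   [generate_feature_bundle()]) for the attended and unattended stream.
#' @param kernels a `gt_kernels` object.
#' @param config a [sim_config()].
#' @param positions optional channels x 3 electrode positions.
#' @param mixing optional precomputed spatial mixing matrix.
#' @param seed optional RNG seed.
#' @return An [eeg_recording()].
#' @export
simulate_trial_eeg <- function(features_att, features_unatt, kernels,
                               config, positions = NULL, mixing = NULL,
                               seed = NULL) {
  with_seed_maybe(seed, {
    lags <- attr(kernels, "lags")
    nchan <- config$n_channels
    n_t <- round(config$duration * config$fs)
    for (space in names(kernels)) {
      for (fb in list(features_att[[space]], features_unatt[[space]])) {
        if (!is.null(fb) && ncol(fb$data) != n_t) {
          abort_bad_arg("feature stream sample count does not match config.")
        }
      }
    }
    signal <- matrix(0, nchan, n_t)
    for (space in names(kernels)) {
      k <- kernels[[space]]
      if (k$gain_att != 0) {
        signal <- signal + k$gain_att *
          convolve_kernel(features_att[[space]], k$weights, lags)
      }
      if (k$gain_unatt != 0) {
        signal <- signal + k$gain_unatt *
          convolve_kernel(features_unatt[[space]], k$weights, lags)
      }
    }
    positions <- positions %||% synthetic_positions(nchan)
    noise_scale <- if (!is.null(config$noise_sd)) {
      config$noise_sd
    } else {
      psig <- mean(signal^2)
      if (psig == 0) {
        abort_bad_arg(paste0("all gains are zero and no `noise_sd` is set; ",
          "the SNR-based noise scale is undefined."))
      }
      sqrt(psig * 10^(-config$snr_db / 10))
    }
    if (noise_scale > 0) {
      mixing <- mixing %||% spatial_mixing(positions)
      src <- t(vapply(seq_len(nchan), function(i) {
        pink_noise(n_t, config$noise_alpha)
      }, numeric(n_t)))
      noise <- mixing %*% src
      noise <- noise / stats::sd(as.vector(noise))
      signal <- signal + noise_scale * noise
    }
    eeg_recording(signal, fs = config$fs,
      labels = sprintf("CH%02d", seq_len(nchan)), positions = positions)
  })
}

#' Generate a complete synthetic two-talker study
#'
#' Produces, for every subject and trial, two talker streams (alignments
#' and feature bundles), the attended-talker assignment (counterbalanced:
#' each talker is attended in exactly half the trials, block-wise), and
#' the simulated EEG. The whole study is a pure function of
#' `(config, kernels, seed)`.
#'
#' @param config a [sim_config()].
#' @param kernels optional `gt_kernels`; by default kernels are generated
#'   from the config's seed stream with the headline gain configuration
#'   (acoustic gains equal across streams, phonetic-feature gains 1 and 0)
#'   and calibrated so the per-space components have equal RMS.
#' @param inventory a [phoneme_inventory()].
#' @param gains passed to [ground_truth_kernels()] when `kernels` is NULL.
#' @param support_ms passed to [ground_truth_kernels()].
#' @return A study tibble (class `trf_study`): one row per subject x
#'   trial with columns `subject`, `trial`, `attended`, list-columns
#'   `features_att`, `features_unatt`, `eeg`. The config, kernels and
#'   inventory ride along as attributes.
#' @export
make_study <- function(config, kernels = NULL,
                       inventory = phoneme_inventory(),
                       gains = list(s = c(1, 1), f = c(1, 0)),
                       support_ms = c(30, 280)) {
  withr::with_seed(config$seed, {
    # each talker carries its own phoneme-to-spectrum templates: the two
    # talkers of the experiment have markedly different acoustics, so the
    # same phoneme sounds different across streams
    templates <- list(F = phoneme_templates(config$n_bands, inventory),
      M = phoneme_templates(config$n_bands, inventory))
    positions <- synthetic_positions(config$n_channels)
    mixing <- spatial_mixing(positions)
    if (is.null(kernels)) {
      probe_align <- generate_phoneme_sequence(config$duration,
        config$phoneme_rate, inventory)
      probe <- generate_feature_bundle(probe_align, config, inventory,
        templates$F)
      kernels <- ground_truth_kernels(config, gains = gains,
        support_ms = support_ms, inventory = inventory,
        calibration = probe)
    }
    n_half <- config$n_trials %/% 2L
    rows <- vector("list", config$n_subjects * config$n_trials)
    idx <- 0L
    for (subj in seq_len(config$n_subjects)) {
      for (tr in seq_len(config$n_trials)) {
        bundles <- lapply(c(F = "F", M = "M"), function(talker) {
          al <- generate_phoneme_sequence(config$duration,
            config$phoneme_rate, inventory)
          generate_feature_bundle(al, config, inventory,
            templates[[talker]])
        })
        att <- if (tr <= n_half) "F" else "M"
        unatt <- setdiff(c("F", "M"), att)
        eeg <- simulate_trial_eeg(bundles[[att]], bundles[[unatt]],
          kernels, config, positions = positions, mixing = mixing)
        idx <- idx + 1L
        rows[[idx]] <- tibble::tibble(
          subject = subj, trial = tr, attended = att,
          features_att = list(bundles[[att]]),
          features_unatt = list(bundles[[unatt]]),
          eeg = list(eeg)
        )
      }
    }
    study <- dplyr::bind_rows(rows)
    attr(study, "config") <- config
    attr(study, "kernels") <- kernels
    attr(study, "inventory") <- inventory
    class(study) <- c("trf_study", class(study))
    study
  })
}

#' Correlation between an estimated TRF and the ground-truth kernel
#'
#' Rescales the estimated weights from z-scored-predictor units back to
#' raw feature units (dividing each predictor's kernel by the feature's
#' study-average standard deviation) and correlates the flattened kernel
#' with the ground truth.
#'
#' @param model a `trf_model` fit on z-scored predictors.
#' @param kernels a `gt_kernels` object.
#' @param space feature-space tag to compare.
#' @param features_ref list of [feature_set()]s used to estimate the raw
#'   predictor SDs (e.g. the attended features of all trials).
#' @return Pearson correlation of the flattened kernels.
#' @export
kernel_recovery_correlation <- function(model, kernels, space,
                                        features_ref) {
  w_true <- kernels[[space]]$weights
  sds <- rowMeans(vapply(features_ref, function(f) {
    apply(f$data, 1L, stats::sd)
  }, numeric(dim(w_true)[2])))
  w_hat <- model$weights
  for (p in seq_len(dim(w_hat)[2])) {
    w_hat[, p, ] <- w_hat[, p, ] / max(sds[p], 1e-12)
  }
  stats::cor(as.vector(w_hat), as.vector(w_true))
}
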