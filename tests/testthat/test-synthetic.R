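test_that("phoneme sequences are valid, seed-deterministic renewal processes", {
  al <- generate_phoneme_sequence(60, 10, seed = 50)
  expect_true(all(diff(al$onset) > 0))
  expect_true(all(al$offset[-nrow(al)] <= al$onset[-1] + 1e-12))
  expect_lte(max(al$offset), 60)
  # count near duration * rate (durations are clipped lognormal around 1/rate)
  expect_gt(nrow(al), 600 * 0.7)
  expect_lt(nrow(al), 600 * 1.4)
  # same seed -> bit-identical
  expect_identical(al, generate_phoneme_sequence(60, 10, seed = 50))
  expect_false(identical(al, generate_phoneme_sequence(60, 10, seed = 51)))
  # degenerate rate: one forced phoneme spanning at most the duration
  one <- generate_phoneme_sequence(1, 0, force_label = "AA")
  expect_equal(nrow(one), 1)
  expect_lte(one$offset, 1)
  expect_equal(one$phoneme, "AA")
  # durations respect the 30-300 ms clip
  durs <- al$offset - al$onset
  expect_gte(min(durs), 0.03 - 1e-12)
  expect_lte(max(durs), 0.3 + 1e-12)
})

test_that("feature bundles have the contracted shapes and coupling behaviour", {
  cfg <- tiny_config(seed = 52, duration = 20)
  inv <- phoneme_inventory()
  al <- generate_phoneme_sequence(20, 10, inv, seed = 53)
  fb <- generate_feature_bundle(al, cfg, inv, seed = 54)
  expect_named(fb, c("s", "sD", "f", "fo", "vc"))
  expect_equal(nrow(fb$f$data), 19)
  expect_equal(nrow(fb$vc$data), 2)
  expect_equal(nrow(fb$s$data), cfg$n_bands)
  expect_equal(ncol(fb$s$data), 20 * cfg$fs)

  # coupling 1: identical phonemes with identical durations give identical
  # spectrogram columns
  cfg1 <- tiny_config(seed = 52, duration = 2, coupling = 1)
  al2 <- tibble::tibble(phoneme = c("S", "S"), onset = c(0.2, 1.2),
    offset = c(0.3, 1.3))
  fb2 <- generate_feature_bundle(al2, cfg1, inv, seed = 55)
  i1 <- round(0.2 * cfg1$fs) + 1; i2 <- round(1.2 * cfg1$fs) + 1
  expect_equal(fb2$s$data[, i1 + 0:5], fb2$s$data[, i2 + 0:5],
    tolerance = 1e-12)

  # coupling 0: spectrogram decorrelated from the phonetic features
  cfg0 <- tiny_config(seed = 52, duration = 30, coupling = 0)
  al3 <- generate_phoneme_sequence(30, 10, inv, seed = 56)
  fb3 <- generate_feature_bundle(al3, cfg0, inv, seed = 57)
  n_t <- ncol(fb3$s$data)
  rmax <- max(abs(cor(t(fb3$s$data[1:4, ]), t(fb3$f$data[1:4, ]))))
  expect_lt(rmax, 3 / sqrt(n_t) * 2)
  expect_error(tiny_config(coupling = 1.2), class = "speechtrf_error_config")
})

test_that("simulated EEG is the exact kernel convolution plus scaled noise", {
  cfg <- tiny_config(seed = 58, n_trials = 1, duration = 6, noise_sd = 0,
    snr_db = NULL)
  inv <- phoneme_inventory()
  kern <- ground_truth_kernels(cfg, gains = list(s = c(1, 0)), seed = 59)
  al <- generate_phoneme_sequence(6, 10, inv, seed = 60)
  fa <- generate_feature_bundle(al, cfg, inv, seed = 61)
  fu <- generate_feature_bundle(
    generate_phoneme_sequence(6, 10, inv, seed = 62), cfg, inv, seed = 63)
  eeg <- simulate_trial_eeg(fa, fu, kern, cfg)
  conv <- speechtrf:::convolve_kernel(fa$s, kern$s$weights,
    attr(kern, "lags"))
  expect_equal(eeg$data, conv, ignore_attr = TRUE)

  # all gains zero + fixed noise SD -> pure noise at that SD (+-10%)
  cfg_n <- tiny_config(seed = 58, n_trials = 1, duration = 6,
    noise_sd = 2.5, snr_db = NULL)
  kern0 <- ground_truth_kernels(cfg_n, gains = list(s = c(0, 0)), seed = 59)
  eeg_n <- simulate_trial_eeg(fa, fu, kern0, cfg_n, seed = 64)
  expect_gt(sd(eeg_n$data), 2.25); expect_lt(sd(eeg_n$data), 2.75)

  # doubling a gain doubles that component (checked by subtraction)
  kern2 <- kern
  kern2$s$gain_att <- 2
  eeg2 <- simulate_trial_eeg(fa, fu, kern2, cfg)
  expect_equal(eeg2$data - eeg$data, conv, ignore_attr = TRUE,
    tolerance = 1e-12)

  # mismatched sample counts error
  fa_bad <- fa
  fa_bad$s <- feature_set(fa$s$data[, 1:100], cfg$fs, "s")
  expect_error(simulate_trial_eeg(fa_bad, fu, kern, cfg), "sample count")
})

test_that("SNR-scaled noise hits the requested power ratio", {
  cfg <- tiny_config(seed = 65, n_trials = 1, duration = 10, snr_db = 0)
  st <- make_study(cfg, gains = list(s = c(1, 0)))
  cfg0 <- tiny_config(seed = 65, n_trials = 1, duration = 10, noise_sd = 0,
    snr_db = NULL)
  st0 <- make_study(cfg0, gains = list(s = c(1, 0)))
  p_sig <- mean(st0$eeg[[1]]$data^2)
  p_tot <- mean(st$eeg[[1]]$data^2)
  # at 0 dB the noise power matches the signal power (total ~ 2x signal)
  expect_gt(p_tot / p_sig, 1.6); expect_lt(p_tot / p_sig, 2.4)
})

test_that("studies are complete, counterbalanced and seed-determined", {
  cfg <- tiny_config(seed = 66, n_subjects = 2, n_trials = 4, duration = 4)
  st <- make_study(cfg)
  expect_equal(nrow(st), 8)
  expect_equal(unique(table(st$subject)), 4L)
  for (s in 1:2) {
    att <- st$attended[st$subject == s]
    expect_equal(sum(att == "F"), 2)
    expect_equal(sum(att == "M"), 2)
  }
  st2 <- make_study(cfg)
  expect_identical(st$eeg[[5]]$data, st2$eeg[[5]]$data)
  expect_identical(st$features_unatt[[3]]$f$data,
    st2$features_unatt[[3]]$f$data)
  st3 <- make_study(tiny_config(seed = 67, n_subjects = 2, n_trials = 4,
    duration = 4))
  expect_false(identical(st$eeg[[1]]$data, st3$eeg[[1]]$data))
})

test_that("ground-truth kernels respect support, gains and calibration", {
  cfg <- tiny_config(seed = 68)
  kern <- ground_truth_kernels(cfg,
    gains = list(s = c(1, 1), f = c(1, 0)),
    support_ms = list(s = c(30, 280), f = c(150, 200)), seed = 69)
  lag_ms <- attr(kern, "lags") / cfg$fs * 1000
  outside <- lag_ms < 150 | lag_ms > 200
  expect_true(all(kern$f$weights[outside, , ] == 0))
  expect_true(any(kern$f$weights != 0))
  expect_equal(kern$f$gain_unatt, 0)
  expect_error(
    ground_truth_kernels(cfg, gains = list(s = c(1, -1))), ">= 0")
  expect_error(
    ground_truth_kernels(cfg, gains = list(s = c(1, 1)),
      support_ms = c(0, 500)), "inside the analysis lag window")
})
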