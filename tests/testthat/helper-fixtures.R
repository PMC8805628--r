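# Shared fixtures: tiny study configurations and toy signal builders.
# Everything is generated in code at test time.

tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    n_subjects = 2, n_trials = 4, duration = 8, fs = 64,
    n_channels = 6, n_bands = 8, seed = seed
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

toy_alignment <- function(phonemes = c("B", "AA", "T"),
                          onsets = c(0.1, 0.3, 0.6),
                          dur = 0.15) {
  tibble::tibble(phoneme = phonemes, onset = onsets, offset = onsets + dur)
}

# A noiseless single-space study for exact model checks.
noiseless_study <- function(seed = 5, n_trials = 4, duration = 8) {
  cfg <- tiny_config(seed = seed, n_trials = n_trials, duration = duration,
    noise_sd = 0, snr_db = NULL)
  make_study(cfg, gains = list(s = c(1, 0)))
}

# Random eeg_recording on a unit-sphere layout.
random_eeg <- function(n_ch = 8, n_t = 256, fs = 128, seed = 1,
                       mastoids = NULL) {
  withr::with_seed(seed, {
    eeg_recording(matrix(rnorm(n_ch * n_t), n_ch), fs = fs,
      positions = speechtrf:::synthetic_positions(n_ch),
      mastoids = mastoids)
  })
}
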