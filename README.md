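# speechtrf

Forward temporal-response-function (TRF) analysis of EEG responses to
continuous speech in two-talker ("cocktail party") listening, with
partial-correlation variance partitioning and a permutation /
Wilcoxon / FDR / Bayes-factor statistics layer — plus a seeded synthetic
study generator with known ground truth, so every stage of the pipeline
has a parameter-recovery test.

## The scientific problem

When two people speak at once, a listener's EEG tracks the attended
talker. A long-standing question is *at which level of representation*
attention operates: on the raw acoustics, or on categorical phonetic
features computed later in the processing hierarchy. The approach
implemented here fits encoding models

```
r(t, n) = Σ_τ w(τ, n) · s(t − τ) + ε(t, n)        (per EEG channel n)
w = (SᵀS + λI)⁻¹ Sᵀ r                              (ridge reverse correlation)
```

for four stimulus representations — mel spectrogram `s`, its half-wave
rectified derivative `sD` (acoustic onsets), a 19-feature binary
articulatory matrix `f`, and a phoneme-onset impulse train `fo` — over
0–300 ms of stimulus–response lags, with leave-one-trial-out
cross-validation of λ (one λ per subject; per-trial TRFs averaged across
training trials). Each space's *unique predictive power* is the partial
correlation between recorded EEG and that space's cross-validated
prediction, controlling for the other spaces' predictions, averaged over
channels. Significance comes from trial-derangement permutation nulls
(predictions scored against a *different* trial's EEG, 1000×/subject,
resampled group means), two-tailed Wilcoxon signed-rank tests with
Benjamini–Hochberg FDR, and JZS Bayes factors (Cauchy scale 0.707).

The package is aimed at auditory-neuroscience users who want a tested,
scriptable re-implementation of this analysis chain, and at
methodologists who want to probe its behavior on synthetic data with
known kernels and attention gains.

## A worked example

A small synthetic study (5 subjects, 4 trials × 6 s at 32 Hz — sizes
chosen so this runs in under a minute):

```r
library(speechtrf)

cfg <- study_config(
  sim = sim_config(n_subjects = 5, n_trials = 4, duration = 6, fs = 32,
                   n_channels = 4, seed = 9),
  lambda_joint = c(1, 100), lambda_partial = c(1, 100),
  window_ms = 150, n_perm = 60, n_group = 200, seed = 9
)
res <- run_study(cfg)

dplyr::summarise(dplyr::group_by(res$unique, feature_space, condition),
                 partial_r = mean(partial_r), p_perm = dplyr::first(p_perm))
#>    feature_space  condition partial_r  p_perm
#>  1             f   attended   0.20350 0.00498
#>  2             f unattended   0.00962 0.14925
#>  5             s   attended   0.14433 0.00498
#>  6             s unattended   0.17884 0.00498
#>  ...
```

The generator's headline configuration drives the EEG with an acoustic
kernel applied equally to both talker streams and a phonetic-feature
kernel applied to the attended stream only. The output shows exactly
that structure recovered: the spectrogram's unique contribution is
significant in both conditions and of similar size (≈0.14–0.18,
permutation p ≈ 0.005), while the phonetic features contribute only for
attended speech (0.20 vs 0.01; unattended p = 0.15). The statistical
report mirrors a joint-model comparison table:

```r
res$stat_report[c(1, 15, 17), c("comparison", "condition", "observed",
                                "p_wilcoxon", "z", "bf10")]
#>                 comparison condition observed p_wilcoxon     z  bf10
#> 1                  s+f > s  attended   0.0858     0.0625 2.023 20.47
#> 2 s: attended > unattended  contrast  -0.0345     0.6250 -0.674 0.58
#> 3 f: attended > unattended  contrast   0.1939     0.0625 2.023 14.69
```

With only 5 subjects the exact two-tailed Wilcoxon cannot go below
p = 0.0625, but the Bayes factors already separate the real effects
(BF₁₀ ≈ 15–20 for the phonetic comparisons) from the null ones
(BF₁₀ ≈ 0.5 for the acoustic attention contrast). `write_report(res,
dir)` serializes all tables as CSV with a JSON manifest;
`plot_unique_contribution(res$unique)` and
`plot_windowed_contribution(res$windowed)` draw the standard box plots.

Real data enter through the same containers: `read_wav()` +
`mel_spectrogram()` / `half_wave_derivative()` for audio,
`read_alignment()` (TSV or Praat TextGrid) + `phonetic_features()` for
phoneme streams, `read_eeg()` + `preprocess_eeg()` (mastoid
re-reference, SD-ratio bad-channel interpolation, resampling to 128 Hz,
0.2–8 Hz zero-phase Kaiser FIR) for EEG.

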