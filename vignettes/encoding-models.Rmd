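---
title: "Forward TRF encoding models and variance partitioning for two-talker EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward TRF encoding models and variance partitioning for two-talker EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechtrf)
library(dplyr)
```

## The model

When a listener attends to one of two concurrent talkers, the EEG tracks
the ongoing speech. The forward (encoding) model treats each EEG channel
as a linear, time-lagged transformation of a multivariate stimulus
representation:

$$ r(t, n) = \sum_{\tau} w(\tau, n)\, s(t - \tau) + \epsilon(t, n), $$

where $r(t, n)$ is channel $n$ at sample $t$, $s(t-\tau)$ is the stimulus
representation at lag $\tau$, and the kernel $w(\tau, n)$ is the temporal
response function (TRF). The kernel is estimated by reverse correlation
with ridge regression on the lagged design matrix $S$:

$$ w = (S^\top S + \lambda I)^{-1} S^\top r. $$

Four stimulus representations are compared, two acoustic and two
phonetic:

* `s` — a 31-band mel spectrogram with logarithmic compression;
* `sD` — its half-wave rectified temporal derivative (acoustic onsets);
* `f` — a 19-dimensional binary matrix of articulatory phonetic features
  (manner, place, voicing, vowel position), marked as unit impulses at
  phoneme onsets;
* `fo` — a univariate impulse train at all phoneme onsets (onset timing
  without category information).

A fifth space, `vc`, marks phonemes only as vowels or consonants and is
used as a control: if the full feature set `f` adds predictive power
beyond `vc`, the EEG carries information about specific articulatory
categories, not merely the vowel/consonant distinction.

The analysis has two stages. Stage one compares *joint* models (does
stacking `f` onto acoustic predictors improve EEG prediction?). Stage two
isolates each space's *unique predictive power*: the partial correlation,
per channel, between the recorded EEG and the space's cross-validated
prediction while controlling for the other spaces' predictions, averaged
over channels. A second route to the same quantity — fit a joint model on
the control spaces, subtract its prediction, and model the residual EEG
with the target space — is provided as a consistency check
(`residual_unique_contribution()`).

## Estimation choices

**Per-trial fitting with cross-trial averaging.** For each held-out
trial, one TRF is fit per training trial and the training TRFs are
averaged before predicting the held-out trial; the ridge parameter
maximizes the Pearson correlation between predicted and actual EEG
averaged over all trials and channels, one $\lambda$ per subject. Ties
break toward the smaller $\lambda$ (less smoothing bias). The default
grids are decades $10^{-1}\dots10^6$ for model comparison and powers of
two $2^{-2}\dots2^{37}$ for the partial-correlation path.

**Lags.** The window is 0–300 ms; integer lags run from
$\lceil \text{lag}_{\min} f_s \rceil$ to
$\lfloor \text{lag}_{\max} f_s \rfloor$ inclusive (39 lags at 128 Hz).
In the lag-windowed analysis a lag sample falling exactly on an interior
window boundary belongs to the earlier window, so the six 50-ms windows
tile 0–300 ms without overlap, and all models (target and controls) are
refit inside each window.

**Normalization and intercept.** Predictors are z-scored and the EEG
demeaned per trial; no explicit bias column is used. The per-trial
convention matches the per-trial fit-then-average estimator and keeps
each trial's sufficient statistics independent of the fold split; a
training-statistics variant remains available through the `stats`
argument of `normalize_features()`. Constant predictor rows map to zeros
rather than erroring, so degenerate features (e.g. a feature never
active in a short trial) are silently inert.

**Numerical route.** For each trial the eigendecomposition of $S^\top S$
is computed once, making the whole $\lambda$ grid and all leave-one-out
folds cheap; `ridge_fit()` itself solves the regularized normal
equations directly and `lambda = 0` on a rank-deficient design raises an
explicit singularity error rather than returning a pseudo-inverse.

## The statistics layer

Chance level for a unique contribution is established by a
*trial-derangement permutation null*: the target space's held-out
predictions are permuted across trials so that every prediction is
scored against a different trial's EEG (a derangement — no trial maps to
itself), the statistic is recomputed (1000 permutations per subject by
default), and a group-level null is built by resampling one value per
subject with replacement into each of 1000 group means. Empirical p
values use the add-one correction $(1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n)$, so they are never exactly zero. Paired
comparisons (model vs baseline, attended vs unattended) use the
two-tailed Wilcoxon signed-rank test — exact null distribution for
$n \le 25$ without ties, normal approximation with tie correction
otherwise, zero differences dropped — with Benjamini–Hochberg FDR
correction across each comparison family, plus a JZS Bayes factor
(Cauchy prior on the standardized effect, scale 0.707) computed by
adaptive quadrature. BF$_{10} > 3$ is read as evidence for a difference,
$< 1/3$ as evidence for the null.

A property of the derangement null worth knowing: with very few trials
per subject (around six) the derangement statistics are mutually
correlated (on the order of $1/n_\text{trials}$) while uncorrelated with
the matched statistic, which makes the group test anti-conservative
(empirically ~0.10 rejection at $\alpha = 0.05$). At realistic trial
counts (20–40 per subject) the test is calibrated — the type-I rate
measured over 400 null simulations at 20 trials/subject is 0.05 — so
permutation inference should be run on studies with at least ~20 trials.

## What the synthetic generator emulates

`make_study()` produces a complete two-talker study with known ground
truth. Per trial, two independent streams (talkers "F" and "M") each get
a renewal phoneme sequence — log-normal durations around `1/rate`
(default 12 phonemes/s, natural speech range), clipped to 30–300 ms —
and a full feature bundle. The synthetic spectrogram mixes per-phoneme
spectral templates with smooth $1/f$ band noise, weighted by a coupling
coefficient (default 0.5), so acoustics are correlated with, but not
determined by, the phonetic categories. Each talker carries its *own*
template set: the experiment this emulates used a male and a female
talker with markedly different acoustics, and this intra-phoneme
acoustic variability across talkers is precisely what makes the unique
contribution of `f` separable from acoustic redundancy. With shared
templates the phonetic features re-explain acoustic variance that the
finitely-sampled control models miss, and a spurious "unattended
phonetic" effect appears — a useful illustration of the redundancy
confound the two-talker design addresses.

EEG is generated as the lag-limited convolution of the attended (and
gain-scaled unattended) feature streams with smooth random kernels
(Gabor-like bumps, support confined to 30–280 ms by default, spatially
smooth channel loadings), plus spatially correlated $1/f^\alpha$
Gaussian noise ($\alpha = 1$). The headline configuration applies the
acoustic kernel to both streams at equal gain and the phonetic-feature
kernel to the attended stream only — attention acts on the categorical
representation, not the acoustics. The unattended acoustic gain
defaults to 1.0 (the measurement itself found no attention effect on
isolated acoustic encoding); it is exposed in the `gains` argument.
Kernels are calibrated on a probe stimulus so each space's component has
unit RMS, making gains comparable across spaces, and the noise scale is
set from a target SNR (default 0 dB — equal signal and noise power).

What the generator does *not* emulate: real spectro-temporal speech
statistics (templates are random smooth patterns), coarticulation,
eye-blink/muscle artifacts, inter-subject anatomical variability beyond
random kernels, and the very low single-trial SNR of real EEG (at
realistic $-20$ dB the desk-scale studies used here would need far more
data). Passing tests therefore demonstrate that the estimation and
inference machinery recovers known structure under the model's own
assumptions — not that real EEG would yield the same effect sizes.

## Problem sizes used by the tests and the acceptance script

Simulations are sized to run comfortably on a single CPU while keeping
every procedure in its valid regime; these sizes are stated here as the
package's chosen desk scale.

* *Kernel recovery*: 1 subject, 20 trials x 30 s at 128 Hz, 32 channels,
  0 dB SNR, attended-only acoustic kernel — a pure identification
  setting; cross-validated TRF vs ground truth correlates > 0.9.
* *Attention pattern*: 12 subjects, 6 trials x 12 s, 16 channels, at a
  32 Hz analysis rate — the 0.2–8 Hz band-limited signals are fully
  represented at 32 Hz, and the lag grid still spans 0–300 ms. Power for
  the attended-vs-unattended Wilcoxon on `f` is estimated over 20 seeded
  replicates; with equal phonetic gains the same test rejects at the
  nominal rate.
* *Lag localization*: 8 subjects, 6 trials x 15 s at 128 Hz, phonetic
  kernel confined to 150–200 ms; the attended-unattended contrast peaks
  in that 50-ms window.
* *Type-I calibration*: 400 null runs of 6 subjects x 20 trials.

The full experiment scale (40 one-minute trials, 128 channels, the
complete joint-model set at 31 bands x 39 lags) is reachable through the
same configuration objects but is compute-hungry in interpreted R — the
four-space joint design has 3198 columns per trial — so the shipped
tests exercise the identical code paths at the sizes above.

## A small worked example

```{r example, eval = FALSE}
cfg <- study_config(
  sim = sim_config(n_subjects = 5, n_trials = 4, duration = 6, fs = 32,
    n_channels = 4, seed = 9),
  lambda_joint = c(1, 100), lambda_partial = c(1, 100),
  window_ms = 150, n_perm = 60, n_group = 200, seed = 9
)
res <- run_study(cfg)
res$stat_report
plot_unique_contribution(res$unique)
```

The `stat_report` tibble mirrors the joint-model comparison table: one
row per comparison and condition with the observed mean difference,
Wilcoxon p and z, FDR-adjusted p and BF$_{10}$, plus the four
attended-vs-unattended contrasts and the `f` vs `vc` control.

## Known limitations

* Trial-derangement inference is anti-conservative below ~10 trials per
  subject (see above); `run_study()` does not warn about this.
* The unique-contribution decomposition is not a variance partition in
  the additive sense: unique contributions need not sum to the joint
  model's accuracy, and only sign/ordering claims are supported.
* The windowed analysis inherits the temporal smearing of
  autocorrelated stimuli; adjacent windows are not independent.
* `read_wav()` handles PCM/float RIFF only; `read_textgrid()` parses
  IntervalTiers of the long text format only.
* BDF acquisition files are not read; convert to the TSV interchange
  format first.
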