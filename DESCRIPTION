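Package: speechtrf
Title: Temporal Response Function Encoding Models and Variance
    Partitioning for Continuous-Speech EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward (encoding) temporal response function analysis of EEG
    responses to continuous speech in two-talker listening. Computes acoustic
    (mel spectrogram and its half-wave rectified derivative) and phonetic
    (articulatory feature, phoneme onset, vowel/consonant) stimulus
    representations, fits ridge-regression reverse-correlation models with
    leave-one-trial-out cross-validated regularization, quantifies each
    representation's unique predictive power by partial-correlation variance
    partitioning (including lag-windowed and residual-EEG variants), and
    provides a statistics layer with trial-derangement permutation nulls,
    group-level resampled means, Wilcoxon signed-rank tests, Benjamini-
    Hochberg false discovery rate correction and JZS Bayes factors. Includes
    a seeded synthetic two-talker study generator with known ground-truth
    kernels and attention gains for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    knitr,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
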