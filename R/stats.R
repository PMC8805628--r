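# Statistics layer: trial-derangement permutation nulls, group-level
# resampled-mean nulls, two-tailed Wilcoxon signed-rank, Benjamini-
# Hochberg FDR, and JZS Bayes factors for paired designs.

# A derangement of 1..n (no fixed points), by rejection sampling.
sample_derangement <- function(n) {
  if (n < 2L) abort_bad_arg("a derangement needs at least 2 elements.")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Subject-level permutation null by trial derangement
#'
#' Builds a null distribution of the prediction-accuracy statistic by
#' permuting the predicted EEG across trials so that every prediction is
#' matched to the actual EEG of a *different* trial (a derangement), then
#' recomputing the statistic. Defaults to the channel-averaged Pearson
#' correlation between prediction and actual EEG, concatenated over trials.
#'
#' @param predicted list (one per trial) of channels x samples predicted
#'   EEG matrices.
#' @param actual list of channels x samples actual EEG matrices.
#' @param n_perm number of permutations (default 1000).
#' @param statistic function `(actual, predicted) -> scalar` evaluated on
#'   the trial lists; `NULL` uses the default — the per-trial, per-channel
#'   Pearson correlation averaged over trials and channels (the same
#'   metric the cross-validation procedure averages).
#' @param seed RNG seed for reproducibility.
#' @return A `null_distribution`: list with `null` (numeric vector of
#'   length `n_perm`), `observed`, and `statistic` label.
#' @export
permutation_null_subject <- function(predicted, actual, n_perm = 1000,
                                     statistic = NULL, seed = NULL) {
  n <- length(predicted)
  if (n < 2L || length(actual) != n) {
    abort_bad_arg("need matched predicted/actual lists with >= 2 trials.")
  }
  with_seed_maybe(seed, {
    if (is.null(statistic)) {
      # Default statistic: per-trial, per-channel correlation averaged
      # over trials and channels. All trial-pair correlations are
      # precomputed once, so each derangement is an O(n) table lookup.
      nchan <- nrow(actual[[1]])
      stat_fast <- local({
        cs <- function(m) {
          m <- sweep(m, 1L, rowMeans(m))
          m / sqrt(rowSums(m^2))
        }
        pc <- lapply(predicted, cs)
        ac <- lapply(actual, cs)
        r_pair <- array(0, c(n, n, nchan)) # r_pair[i,j,] = cor(pred_i, act_j)
        for (i in seq_len(n)) {
          for (j in seq_len(n)) {
            r_pair[i, j, ] <- rowSums(pc[[i]] * ac[[j]])
          }
        }
        function(perm) {
          acc <- 0
          for (j in seq_len(n)) acc <- acc + mean(r_pair[perm[j], j, ])
          acc / n
        }
      })
      observed <- stat_fast(seq_len(n))
      null <- vapply(seq_len(n_perm), function(k) {
        stat_fast(sample_derangement(n))
      }, numeric(1))
    } else {
      observed <- statistic(actual, predicted)
      null <- vapply(seq_len(n_perm), function(k) {
        statistic(actual, predicted[sample_derangement(n)])
      }, numeric(1))
    }
    structure(
      list(null = null, observed = observed,
        statistic = "channel-mean prediction accuracy"),
      class = "null_distribution"
    )
  })
}

#' Group-level resampled-mean null and empirical p value
#'
#' Builds a null distribution of group means by drawing, for each of
#' `n_group` resamples, one value at random (with replacement) from every
#' subject's individual null distribution and averaging across subjects.
#' The right-tailed empirical p value uses the add-one correction:
#' `p = (1 + #\{null >= observed\}) / (1 + n_group)`.
#'
#' @param subject_nulls list of numeric vectors (one per subject) or a
#'   list of `null_distribution` objects.
#' @param observed observed group mean statistic.
#' @param n_group number of resampled group means (default 1000).
#' @param seed RNG seed.
#' @return List with `p`, `null` (group-mean null vector) and `observed`.
#' @export
group_null_and_p <- function(subject_nulls, observed, n_group = 1000,
                             seed = NULL) {
  if (length(subject_nulls) == 0L) abort_bad_arg("no subject nulls given.")
  vals <- lapply(subject_nulls, function(x) {
    if (inherits(x, "null_distribution")) x$null else as.numeric(x)
  })
  with_seed_maybe(seed, {
    draws <- vapply(vals, function(v) {
      v[sample.int(length(v), n_group, replace = TRUE)]
    }, numeric(n_group))
    null <- rowMeans(draws)
    list(
      p = (1 + sum(null >= observed)) / (1 + n_group),
      null = null,
      observed = observed
    )
  })
}

#' Two-tailed Wilcoxon signed-rank test for paired samples
#'
#' Signed-rank test on the paired differences `a - b`; zero differences
#' are dropped. The exact null distribution is used for n <= 25 when the
#' absolute differences are untied, otherwise the normal approximation
#' with tie correction. The z statistic always carries the sign of the
#' rank-sum deviation (positive when `a` tends to exceed `b`).
#'
#' @param a,b paired numeric vectors (n >= 5 after dropping zeros).
#' @return A tibble with `statistic` (W+, the positive rank sum), `z`,
#'   `p`, and `n` (pairs used).
#' @export
wilcoxon_two_tailed <- function(a, b) {
  if (length(a) != length(b)) abort_bad_arg("`a` and `b` must be paired.")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    abort_bad_arg("all paired differences are zero.",
      class = "speechtrf_error_degenerate")
  }
  if (n < 5L) abort_bad_arg("need at least 5 nonzero paired differences.")
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  exact <- n <= 25L && !any(duplicated(abs(d)))
  if (exact) {
    # psignrank gives the exact null CDF of W+ for untied ranks
    p_lo <- stats::psignrank(w_pos, n)
    p_hi <- 1 - stats::psignrank(w_pos - 1, n)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  tibble::tibble(statistic = w_pos, z = z, p = p, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p values (monotone, capped at 1).
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p values in (0, 1].
#' @return Adjusted p values, same length and order as `p`.
#' @export
fdr_bh <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) {
    abort_bad_arg("p values must lie in (0, 1].")
  }
  stats::p.adjust(p, method = "BH")
}

#' JZS Bayes factor for a paired comparison
#'
#' Bayes factor BF10 for the paired t statistic under the
#' Jeffreys-Zellner-Siow prior: a Cauchy prior with the given scale on the
#' standardized effect size, equivalently a normal-on-effect with
#' inverse-gamma(1/2, scale^2/2) mixing variance. Computed by adaptive
#' quadrature of the marginal-likelihood ratio. BF10 above 3 is
#' conventionally read as evidence for a difference, below 1/3 as evidence
#' for the null.
#'
#' @param a,b paired numeric vectors (n >= 2).
#' @param scale Cauchy prior scale on the effect size (default 0.707,
#'   i.e. sqrt(2)/2).
#' @return Scalar BF10.
#' @export
jzs_bf_paired <- function(a, b, scale = 0.707) {
  if (length(a) != length(b)) abort_bad_arg("`a` and `b` must be paired.")
  d <- a - b
  n <- length(d)
  if (n < 2L) abort_bad_arg("need at least 2 pairs.")
  sd_d <- stats::sd(d)
  if (sd_d < 1e-300) {
    abort_bad_arg("paired differences have zero variance.",
      class = "speechtrf_error_degenerate")
  }
  t <- mean(d) / (sd_d / sqrt(n))
  jzs_bf_from_t(t, n, scale)
}

#' @rdname jzs_bf_paired
#' @param t paired-sample t statistic.
#' @param n number of pairs.
#' @export
jzs_bf_from_t <- function(t, n, scale = 0.707) {
  nu <- n - 1
  # null marginal (up to shared constants): central t density kernel
  m0 <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  # alternative: integrate over the mixing variance g of the effect prior,
  # g ~ inverse-gamma(1/2, scale^2/2)
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      (scale^2 / (2 * pi))^(1 / 2) * g^(-3 / 2) * exp(-scale^2 / (2 * g))
  }
  m1 <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
    abs.tol = 0)$value
  m1 / m0
}
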