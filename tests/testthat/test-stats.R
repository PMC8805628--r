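test_that("permutations are derangements and the null is centred for independent data", {
  withr::with_seed(30, {
    for (n in c(2, 3, 5, 9)) {
      for (k in 1:50) {
        p <- speechtrf:::sample_derangement(n)
        expect_true(all(p != seq_len(n)))
      }
    }
  })
  withr::with_seed(31, {
    pred <- lapply(1:6, function(i) matrix(rnorm(3 * 120), 3))
    act <- lapply(1:6, function(i) matrix(rnorm(3 * 120), 3))
  })
  nd <- permutation_null_subject(pred, act, n_perm = 400, seed = 32)
  se <- sd(nd$null) / sqrt(length(nd$null))
  expect_lt(abs(mean(nd$null)), max(4 * se, 0.02))
  # seed determinism
  nd2 <- permutation_null_subject(pred, act, n_perm = 400, seed = 32)
  expect_identical(nd$null, nd2$null)
  expect_error(permutation_null_subject(pred[1], act[1]), ">= 2 trials")
})

test_that("the fast default permutation statistic equals its explicit recomputation", {
  withr::with_seed(33, {
    pred <- lapply(1:5, function(i) matrix(rnorm(2 * 60), 2))
    act <- lapply(1:5, function(i) matrix(rnorm(2 * 60), 2))
  })
  stat_explicit <- function(actual, predicted) {
    mean(vapply(seq_along(actual), function(i) {
      mean(vapply(1:2, function(ch) {
        cor(predicted[[i]][ch, ], actual[[i]][ch, ])
      }, numeric(1)))
    }, numeric(1)))
  }
  ndA <- permutation_null_subject(pred, act, n_perm = 50, seed = 34)
  ndB <- permutation_null_subject(pred, act, n_perm = 50,
    statistic = stat_explicit, seed = 34)
  expect_equal(ndA$null, ndB$null, tolerance = 1e-12)
  expect_equal(ndA$observed, stat_explicit(act, pred), tolerance = 1e-12)
})

test_that("group-level empirical p behaves at the extremes and the centre", {
  nulls <- withr::with_seed(35, lapply(1:8, function(i) rnorm(500)))
  top <- group_null_and_p(nulls, observed = 10, n_group = 1000, seed = 36)
  expect_equal(top$p, 1 / 1001)
  mid <- group_null_and_p(nulls, observed = 0, n_group = 1000, seed = 36)
  expect_gt(mid$p, 0.4); expect_lt(mid$p, 0.6)
  expect_error(group_null_and_p(list(), 0), "no subject nulls")
})

test_that("group permutation test has nominal type-I error on null data", {
  # full machinery on independent predicted/actual series, 400 null runs,
  # at the study's trial-count regime (20 trials per subject; with very
  # few trials the derangement null is known to run anti-conservative)
  n_runs <- 400
  rej <- withr::with_seed(37, vapply(seq_len(n_runs), function(run) {
    nulls <- lapply(1:6, function(s) {
      pred <- lapply(1:20, function(i) matrix(rnorm(2 * 30), 2))
      act <- lapply(1:20, function(i) matrix(rnorm(2 * 30), 2))
      permutation_null_subject(pred, act, n_perm = 200)
    })
    obs <- mean(vapply(nulls, function(x) x$observed, numeric(1)))
    group_null_and_p(nulls, obs, n_group = 200)$p < 0.05
  }, logical(1)))
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("Wilcoxon matches exact enumeration and is antisymmetric", {
  # n = 5, all differences positive: exact two-tailed p = 2/32
  a <- c(5, 6.1, 7.3, 8.6, 9.5); b <- c(1, 2, 3, 4, 4.4)
  wt <- wilcoxon_two_tailed(a, b)
  expect_equal(wt$p, 0.0625)
  expect_gt(wt$z, 0)
  # swapping flips z, keeps p
  wt2 <- wilcoxon_two_tailed(b, a)
  expect_equal(wt2$p, wt$p)
  expect_equal(wt2$z, -wt$z)
  # brute-force enumeration over all 2^n sign flips, n <= 12
  withr::with_seed(38, {
    for (k in 1:5) {
      n <- sample(6:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      d <- x - y
      rk <- rank(abs(d))
      w_obs <- sum(rk[d > 0])
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      w_all <- signs %*% rk
      p_lo <- mean(w_all <= w_obs); p_hi <- mean(w_all >= w_obs)
      p_exact <- min(1, 2 * min(p_lo, p_hi))
      expect_equal(wilcoxon_two_tailed(x, y)$p, p_exact)
    }
  })
  expect_error(wilcoxon_two_tailed(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5)),
    class = "speechtrf_error_degenerate")
})

test_that("Benjamini-Hochberg adjustment matches the hand-computed step-up", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))
  withr::with_seed(39, {
    p <- runif(20)
    adj <- fdr_bh(p)
    expect_true(all(diff(adj[order(p)]) >= -1e-15)) # monotone transform
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
  })
  expect_error(fdr_bh(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("JZS Bayes factors match an independent noncentral-t quadrature", {
  # oracle: BF10 = integral of t-likelihood under the Cauchy effect prior
  # over the central t-likelihood, a different formulation of the same model
  bf_oracle <- function(t, n, r = 0.707) {
    nu <- n - 1
    num <- stats::integrate(function(d) {
      vapply(d, function(dd) {
        suppressWarnings(stats::dt(t, nu, ncp = dd * sqrt(n))) *
          stats::dcauchy(dd, 0, r)
      }, numeric(1))
    }, -Inf, Inf, rel.tol = 1e-10)$value
    num / stats::dt(t, nu)
  }
  for (t in c(0, 1.3, 2.5, 4)) {
    expect_equal(jzs_bf_from_t(t, 14), bf_oracle(t, 14), tolerance = 1e-6)
  }
  expect_lt(jzs_bf_from_t(0, 14), 1)
  expect_gt(jzs_bf_from_t(10, 14), 3)
  # strictly increasing in |t| at fixed n
  bfs <- vapply(seq(0, 6, by = 0.5), jzs_bf_from_t, numeric(1), n = 14)
  expect_true(all(diff(bfs) > 0))
  # paired interface
  withr::with_seed(40, {
    x <- rnorm(14, 1); y <- rnorm(14)
  })
  t_stat <- t.test(x, y, paired = TRUE)$statistic
  expect_equal(jzs_bf_paired(x, y), jzs_bf_from_t(unname(t_stat), 14),
    tolerance = 1e-10)
  expect_error(jzs_bf_paired(c(1, 1), c(0, 0)),
    class = "speechtrf_error_degenerate")
})

test_that("Wilcoxon and Bayes factor agree on strong paired effects", {
  agree <- withr::with_seed(41, vapply(1:20, function(k) {
    x <- rnorm(12, 2); y <- rnorm(12)
    w <- wilcoxon_two_tailed(x, y)$p < 0.05
    b <- jzs_bf_paired(x, y) > 3
    w == b
  }, logical(1)))
  expect_gte(mean(agree), 0.95)
})
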