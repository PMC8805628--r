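test_that("partial correlation reduces to Pearson and matches the closed form", {
  set.seed(20)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(partial_correlation(x, y), cor(x, y))
  # trivariate Gaussian: (rxy - rxz ryz) / sqrt((1-rxz^2)(1-ryz^2))
  n <- 1e5
  sig <- matrix(c(1, .6, .5, .6, 1, .5, .5, .5, 1), 3)
  m <- matrix(rnorm(3 * n), n) %*% chol(sig)
  expect_equal(partial_correlation(m[, 1], m[, 2], m[, 3, drop = FALSE]),
    (0.6 - 0.25) / sqrt(0.75 * 0.75), tolerance = 0.01)
  # inputs orthogonal to Z: partial equals plain Pearson
  z <- matrix(rnorm(200), 100)
  xo <- qr.resid(qr(cbind(1, z)), x)
  yo <- qr.resid(qr(cbind(1, z)), y)
  expect_equal(partial_correlation(xo, yo, z), cor(xo, yo),
    tolerance = 1e-10)
  expect_error(partial_correlation(x, as.vector(z %*% c(1, 2)), z),
    class = "speechtrf_error_degenerate")
})

# Build a minimal space_predictions object from explicit per-trial series.
fake_preds <- function(actual, pred_by_space, subject = 1,
                       condition = "attended") {
  chans <- rownames(actual[[1]])
  if (is.null(chans)) chans <- sprintf("CH%02d", seq_len(nrow(actual[[1]])))
  rows <- lapply(names(pred_by_space), function(sp) {
    cv <- list(actual = actual, predictions = pred_by_space[[sp]],
      channels = chans)
    tibble::tibble(subject = subject, condition = condition, space = sp,
      lambda = 1, mean_r = NA_real_, cv = list(cv))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("space_predictions", class(out))
  out
}

test_that("a target fully explained by a control has no unique contribution", {
  withr::with_seed(21, {
    actual <- lapply(1:3, function(i) matrix(rnorm(2 * 300), 2))
    shared <- lapply(1:3, function(i) matrix(rnorm(2 * 300), 2))
    near <- lapply(shared, function(m) m + 1e-4 * matrix(rnorm(600), 2))
  })
  # exactly collinear target degenerates (documented contract) ...
  preds <- fake_preds(actual, list(f = shared, s = shared))
  expect_error(unique_contribution(preds, "f", "s"),
    class = "speechtrf_error_degenerate")
  # ... and a target carrying no information beyond the control is ~ 0
  preds2 <- fake_preds(actual, list(f = near, s = shared))
  uc <- unique_contribution(preds2, "f", "s")
  expect_lt(abs(uc$partial_r), 0.1)
})

test_that("an independent f-driven component survives partialling out the controls", {
  withr::with_seed(22, {
    fcomp <- lapply(1:4, function(i) matrix(rnorm(2 * 300), 2))
    scomp <- lapply(1:4, function(i) matrix(rnorm(2 * 300), 2))
    noise <- lapply(1:4, function(i) matrix(rnorm(2 * 300), 2))
  })
  actual <- lapply(1:4, function(i) fcomp[[i]] + scomp[[i]] + noise[[i]])
  preds <- fake_preds(actual, list(f = fcomp, s = scomp))
  uc_f <- unique_contribution(preds, "f", "s")
  expect_gt(uc_f$partial_r, 0.3)
  # and pure-noise predictions have none
  preds2 <- fake_preds(actual, list(f = noiseless <- lapply(1:4,
    function(i) matrix(rnorm(2 * 300), 2)), s = scomp))
  uc_n <- unique_contribution(preds2, "f", "s")
  expect_lt(abs(uc_n$partial_r), 0.15)
})

test_that("single-tag joint models reproduce the single-space model exactly", {
  cfg <- tiny_config(seed = 23, n_trials = 3, duration = 6)
  st <- make_study(cfg)
  j <- joint_model_accuracy(st, list("s"), conditions = "attended",
    lambda = c(1, 100), lag_max = 200)
  f <- fit_encoding_models(st, "s", "attended", lambda = c(1, 100),
    lag_max = 200)
  expect_equal(j$mean_r, f$mean_r, tolerance = 1e-12)
  expect_error(joint_model_accuracy(st, list(c("s", "zz"))), "unknown tag")
  expect_error(joint_model_accuracy(st, list(character(0))), "empty")
})

test_that("stacked designs have the summed column counts", {
  cfg <- tiny_config(seed = 24, n_trials = 1)
  st <- make_study(cfg)
  fl <- st$features_att[[1]]
  ld <- lag_matrix(list(fl$s, fl$f, fl$fo), 0, 300)
  nlag <- length(speechtrf:::lag_samples(0, 300, cfg$fs))
  expect_equal(ncol(ld$matrix), (cfg$n_bands + 19 + 1) * nlag)
})

test_that("adding an f component makes the s+f joint model beat s alone", {
  cfg <- tiny_config(seed = 25, n_subjects = 3, n_trials = 4, duration = 10)
  st <- make_study(cfg) # default gains: s both streams, f attended-only
  j <- joint_model_accuracy(st, list("s", c("s", "f")),
    conditions = "attended", lambda = lambda_grid_decades())
  ms <- tapply(j$mean_r, j$model, mean)
  expect_gt(ms[["s+f"]], ms[["s"]])
})

test_that("residual-path contributions mirror the partial-correlation route", {
  cfg <- tiny_config(seed = 26, n_subjects = 2, n_trials = 4, duration = 10)
  st <- make_study(cfg)
  rc <- residual_unique_contribution(st, "f", c("s", "fo"),
    conditions = c("attended", "unattended"),
    lambda = lambda_grid_decades())
  agg <- tapply(rc$residual_r, rc$condition, mean)
  expect_gt(agg[["attended"]], 0.05) # f drives the attended stream
  expect_lt(abs(agg[["unattended"]]), 0.05) # and not the unattended one
  # with a perfect control model (noiseless s-only world) the residual
  # target accuracy collapses to zero-ish
  st0 <- noiseless_study(seed = 27)
  rc0 <- residual_unique_contribution(st0, "f", "s",
    conditions = "attended", lambda = c(1e-6, 1))
  expect_lt(abs(rc0$residual_r[1]), 0.05)
})

test_that("windowed analysis tiles the lag range and recovers the full window", {
  cfg <- tiny_config(seed = 28, n_subjects = 1, n_trials = 3, duration = 6)
  st <- make_study(cfg)
  w <- windowed_unique_contribution(st, "f", "s", width_ms = 50,
    lag_min = 0, lag_max = 300, conditions = "attended",
    lambda = c(1, 100))
  expect_equal(sort(unique(w$win_lo)), seq(0, 250, by = 50))
  expect_equal(sort(unique(w$win_hi)), seq(50, 300, by = 50))
  # the lag samples of consecutive windows are disjoint and cover 0..hi
  fs <- cfg$fs
  all_lags <- unlist(lapply(seq(0, 250, 50), function(lo) {
    lo_eff <- if (lo > 0 && speechtrf:::is_whole(lo * fs / 1000)) {
      (floor(lo * fs / 1000) + 1) * 1000 / fs
    } else lo
    speechtrf:::lag_samples(lo_eff, lo + 50, fs)
  }))
  expect_equal(sort(all_lags), speechtrf:::lag_samples(0, 300, fs))
  # window width equal to the range reproduces the unwindowed result
  w300 <- windowed_unique_contribution(st, "f", "s", width_ms = 300,
    conditions = "attended", lambda = c(1, 100))
  preds <- predictions_per_space(st, c("f", "s"), "attended",
    lambda = c(1, 100))
  uc <- unique_contribution(preds, "f", "s")
  expect_equal(w300$partial_r, uc$partial_r, tolerance = 1e-12)
  expect_error(windowed_unique_contribution(st, "f", "s", width_ms = 70),
    "divide")
})

test_that("self-partialling sanity: a space against itself with no controls is 1", {
  withr::with_seed(29, {
    pred <- lapply(1:3, function(i) matrix(rnorm(2 * 50), 2))
  })
  preds <- fake_preds(pred, list(f = pred))
  uc <- unique_contribution(preds, "f", character(0))
  expect_equal(uc$partial_r, 1)
})
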