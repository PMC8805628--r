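test_that("lag matrix shifts predictors with leading zeros", {
  x <- feature_set(matrix(1:10, 1), fs = 1000, tag = "fo")
  ld <- lag_matrix(x, 0, 2) # lags 0,1,2 samples at 1 kHz
  expect_equal(ncol(ld$matrix), 3)
  expect_equal(ld$matrix[5, ], c(5, 4, 3))
  expect_equal(ld$matrix[1, ], c(1, 0, 0))
  # unit impulse -> shifted identity block
  imp <- feature_set(matrix(c(0, 0, 1, 0, 0, 0), 1), fs = 1000, tag = "fo")
  ldi <- lag_matrix(imp, 0, 3)
  expect_equal(ldi$matrix[3:6, ], diag(4))
})

test_that("0-300 ms at 128 Hz gives 39 lag columns per predictor", {
  x <- feature_set(matrix(rnorm(2 * 200), 2), fs = 128, tag = "s")
  ld <- lag_matrix(x, 0, 300)
  expect_equal(length(ld$lags), 39)
  expect_equal(ld$lags, 0:38)
  expect_equal(ncol(ld$matrix), 2 * 39)
  expect_error(lag_matrix(feature_set(matrix(1:5, 1), fs = 128, tag = "s"),
    0, 300), "longer than the trial")
})

test_that("ridge solutions match a generic regularized least-squares solve", {
  set.seed(12)
  for (k in 1:20) {
    n <- sample(15:40, 1); p <- sample(3:8, 1)
    x <- matrix(rnorm(n * p), n)
    y <- matrix(rnorm(n * 2), n)
    lam <- 10^runif(1, -3, 2)
    ld <- structure(list(matrix = x, lags = seq_len(p) - 1,
      lag_ms = c(0, p - 1), fs = 1000, tags = "fo",
      predictors = "x"), class = "lagged_design")
    fit <- ridge_fit(ld, y, lam)
    # oracle: augmented least squares rbind(X, sqrt(lam) I)
    aug <- qr.solve(rbind(x, sqrt(lam) * diag(p)),
      rbind(y, matrix(0, p, 2)))
    expect_equal(matrix(fit$weights, p), aug, tolerance = 1e-8,
      ignore_attr = TRUE)
  }
  # lambda = 0 equals plain least squares on a well-conditioned system
  x <- matrix(rnorm(30), 10)
  y <- matrix(rnorm(20), 10)
  ld <- structure(list(matrix = x, lags = 0:2, lag_ms = c(0, 2), fs = 1000,
    tags = "fo", predictors = "x"), class = "lagged_design")
  f0 <- ridge_fit(ld, y, 0)
  expect_equal(matrix(f0$weights, 3), qr.solve(x, y), tolerance = 1e-8,
    ignore_attr = TRUE)
})

test_that("orthonormal designs give the closed form w = S'r / (1 + lambda)", {
  q <- qr.Q(qr(matrix(rnorm(50 * 4), 50)))
  y <- matrix(rnorm(50), 50)
  ld <- structure(list(matrix = q, lags = 0:3, lag_ms = c(0, 3), fs = 1000,
    tags = "fo", predictors = "x"), class = "lagged_design")
  fit <- ridge_fit(ld, y, 2.5)
  expect_equal(as.vector(fit$weights), as.vector(crossprod(q, y)) / 3.5,
    tolerance = 1e-10)
})

test_that("weight norms shrink as lambda grows and lambda=0 errors when singular", {
  set.seed(13)
  x <- matrix(rnorm(40 * 5), 40)
  y <- matrix(rnorm(40), 40)
  ld <- structure(list(matrix = x, lags = 0:4, lag_ms = c(0, 4), fs = 1000,
    tags = "fo", predictors = "x"), class = "lagged_design")
  norms <- vapply(10^seq(-2, 4), function(l) {
    sqrt(sum(ridge_fit(ld, y, l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
  xs <- cbind(x[, 1], x[, 1], x[, 2]) # exactly collinear
  lds <- structure(list(matrix = xs, lags = 0:2, lag_ms = c(0, 2), fs = 1000,
    tags = "fo", predictors = "x"), class = "lagged_design")
  expect_error(ridge_fit(lds, y, 0), class = "speechtrf_error_singular")
})

test_that("prediction is linear, zero for zero weights, and exact on noiseless data", {
  cfg <- tiny_config(seed = 14, n_trials = 1, noise_sd = 0, snr_db = NULL)
  st <- make_study(cfg, gains = list(s = c(1, 0)))
  feats <- st$features_att[[1]]$s
  eeg <- st$eeg[[1]]
  zf <- normalize_features(feats)
  ld <- lag_matrix(zf, 0, 300)
  y <- t(eeg$data)
  y <- sweep(y, 2, colMeans(y))
  fit <- ridge_fit(ld, y, 1e-8)
  pred <- predict_response(fit, feats)
  r <- speechtrf:::pearson_cols(t(pred), y)
  expect_true(all(r > 0.999))
  # linearity in the features
  p1 <- predict_response(fit, feats, normalize = FALSE)
  f2 <- feats; f2$data <- 2 * f2$data
  expect_equal(predict_response(fit, f2, normalize = FALSE), 2 * p1,
    tolerance = 1e-12)
  fit0 <- fit; fit0$weights[] <- 0
  expect_true(all(predict_response(fit0, feats) == 0))
  wrong <- st$features_att[[1]]$f
  expect_error(predict_response(fit, wrong),
    class = "speechtrf_error_tag_mismatch")
})

test_that("cross-validation folds average the other trials' single-trial TRFs", {
  cfg <- tiny_config(seed = 15, n_trials = 3, duration = 5)
  st <- make_study(cfg)
  feats <- lapply(st$features_att[1:3], function(fl) list(fl$s))
  cv <- crossval_lambda(feats, st$eeg[1:3], lambda = c(1, 100), lag_min = 0,
    lag_max = 200)
  # recompute fold 2 by hand at the selected lambda
  lam <- cv$lambda
  w <- lapply(c(1, 3), function(i) {
    zf <- normalize_features(st$features_att[[i]]$s)
    ld <- lag_matrix(zf, 0, 200)
    y <- t(st$eeg[[i]]$data); y <- sweep(y, 2, colMeans(y))
    fit <- ridge_fit(ld, y, lam)
    matrix(fit$weights, ncol = dim(fit$weights)[3])
  })
  w_avg <- (w[[1]] + w[[2]]) / 2
  zf2 <- normalize_features(st$features_att[[2]]$s)
  pred2 <- lag_matrix(zf2, 0, 200)$matrix %*% w_avg
  expect_equal(cv$predictions[[2]], t(pred2), tolerance = 1e-10,
    ignore_attr = TRUE)
  expect_error(crossval_lambda(feats[1:2], st$eeg[1:2]), "at least 3")
  expect_error(crossval_lambda(feats, st$eeg[1:3], lambda = numeric(0)),
    "empty lambda")
})

test_that("noiseless synthetic data select the smallest lambda with near-perfect accuracy", {
  st <- noiseless_study(seed = 16)
  feats <- lapply(st$features_att[1:4], function(fl) list(fl$s))
  cv <- crossval_lambda(feats, st$eeg[1:4], lambda = c(1e-4, 1, 1e4))
  expect_equal(cv$lambda, 1e-4)
  expect_gt(cv$mean_r, 0.99)
})

test_that("independent-noise EEG gives chance-level accuracy", {
  cfg <- tiny_config(seed = 17)
  st <- make_study(cfg)
  n_t <- ncol(st$eeg[[1]]$data)
  noise_eeg <- withr::with_seed(99, lapply(st$eeg[1:4], function(e) {
    eeg_recording(matrix(rnorm(length(e$data)), nrow(e$data)), e$fs)
  }))
  feats <- lapply(st$features_att[1:4], function(fl) list(fl$s))
  cv <- crossval_lambda(feats, noise_eeg, lambda = c(1, 100))
  expect_lt(abs(cv$mean_r), 2 / sqrt(n_t))
})

test_that("channel subset means are plain arithmetic means", {
  r <- c(A = 0.2, B = 0.4, C = 0.9, D = -0.1)
  expect_equal(channel_mean_score(r, "C"), 0.9)
  expect_equal(channel_mean_score(rep(0.3, 5)), 0.3)
  expect_equal(channel_mean_score(r, c("A", "B", "D")),
    (0.2 + 0.4 - 0.1) / 3)
  expect_error(channel_mean_score(r, character(0)), "empty")
  expect_error(channel_mean_score(r, "Z"), "unknown")
})
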