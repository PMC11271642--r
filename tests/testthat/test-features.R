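# Window grid, cutting, preprocessing, xDAWN and feature extraction.

test_that("the sliding grid enumerates exactly 81 windows from -5 to 0", {
  g <- window_grid()
  expect_equal(nrow(g), 81)
  expect_equal(g$start[1], -5)
  expect_equal(g$end[1], -4)
  expect_equal(g$start[81], -1)
  expect_equal(g$end[81], 0)
  # brute-force enumeration of starts
  expect_equal(g$start, seq(-5, -1, by = 0.05), tolerance = 1e-12)
  expect_true(all(abs(diff(g$start) - 0.05) < 1e-9))
})

test_that("windows are cut half-open on the sampling grid at absolute times", {
  cfg <- tiny_config(seed = 13)
  std <- generate_subject_task(cfg, 1, "unilateral")
  rec <- std$sets[[1]]$recording
  onset <- 10.0
  w <- cut_windows(rec, onset)
  expect_equal(nrow(w), 81)
  expect_equal(dim(w$data[[1]]), c(8, 500))
  # first window covers absolute [5, 6) s, last [9, 10) s
  i0 <- round(5 * rec$rate) + 1
  expect_identical(w$data[[1]], rec$data[, i0:(i0 + 499)])
  j0 <- round(9 * rec$rate) + 1
  expect_identical(w$data[[81]], rec$data[, j0:(j0 + 499)])
  # insufficient history: skipped with warning
  expect_warning(out <- cut_windows(rec, 4.0), "skipped")
  expect_null(out)
})

test_that("preprocessing standardizes, decimates to 20 samples and band-passes", {
  set.seed(2)
  x <- matrix(rnorm(3 * 500), 3, 500)
  y <- preprocess_window(x)
  expect_equal(dim(y), c(3, 20))
  # constant channel maps to all zeros, not NaN
  x2 <- x
  x2[2, ] <- 7
  y2 <- preprocess_window(x2)
  expect_equal(y2[2, ], rep(0, 20))
  expect_true(all(is.finite(y2)))
  # stop-band sinusoid (8 Hz) is crushed relative to pass-band (2 Hz)
  t <- (0:499) / 500
  p_out <- sum(preprocess_window(rbind(sin(2 * pi * 8 * t)))^2)
  p_in <- sum(preprocess_window(rbind(sin(2 * pi * 2 * t)))^2)
  expect_lt(p_out / p_in, 0.01)
  # DC is removed
  p_dc <- sum(preprocess_window(rbind(1 + 0.001 * sin(2 * pi * 2 * t)))^2)
  expect_true(is.finite(p_dc))
})

test_that("out-of-band attenuation is at least 20 dB across frequencies", {
  t <- (0:499) / 500
  ref <- sum(preprocess_window(rbind(sin(2 * pi * 2 * t)))^2)
  for (f in c(6, 8, 9)) {
    p <- sum(preprocess_window(rbind(sin(2 * pi * f * t)))^2)
    expect_lt(10 * log10(p / ref), -20)
  }
})

test_that("xDAWN matches a dense generalized eigensolver on a toy problem", {
  set.seed(5)
  nch <- 6
  pattern <- c(1, 0.5, -0.3, 0.2, 0, 0.1)
  ramp <- seq(0, -1, length.out = 20)
  windows <- list()
  labels <- character(0)
  for (i in 1:40) {
    lrp <- i <= 20
    w <- matrix(rnorm(nch * 20, 0, 0.5), nch, 20)
    if (lrp) w <- w + outer(pattern, ramp)
    windows[[i]] <- w
    labels[i] <- if (lrp) "LRP" else "NoLRP"
  }
  fit <- fit_xdawn(windows, labels, n_filters = 4)
  # dense oracle: eig(solve(sigma_t) %*% sigma_e)
  evoked <- Reduce(`+`, windows[labels == "LRP"]) / 20
  sigma_e <- tcrossprod(evoked) / 20
  sigma_t <- Reduce(`+`, lapply(windows, tcrossprod)) / (40 * 20)
  oracle <- sort(Re(eigen(solve(sigma_t) %*% sigma_e)$values),
                 decreasing = TRUE)
  expect_lt(max(abs(fit$eigenvalues - oracle[1:4])), 1e-8)
  # first pseudo-channel's average time course tracks the true ramp
  pseudo_avg <- Reduce(`+`, lapply(windows[labels == "LRP"], function(w)
    apply_xdawn(w, fit)))[1, ] / 20
  expect_gt(abs(stats::cor(pseudo_avg, ramp)), 0.9)
})

test_that("xDAWN with n_filters = n_channels spans the full space", {
  set.seed(6)
  windows <- lapply(1:30, function(i) matrix(rnorm(4 * 20), 4, 20))
  labels <- rep(c("LRP", "NoLRP"), 15)
  fit <- fit_xdawn(windows, labels, n_filters = 4)
  expect_equal(dim(fit$weights), c(4, 4))
  expect_gt(abs(det(fit$weights)), 0)
  expect_error(fit_xdawn(windows[1:10], rep("LRP", 10)), "both classes")
  expect_error(fit_xdawn(windows, labels, n_filters = 5), "channels")
})

test_that("applying xDAWN is linear and selection filters pass channels through", {
  set.seed(7)
  fit <- structure(
    list(weights = diag(6)[, 1:4], eigenvalues = rep(1, 4),
         channels = NULL, classes = c("LRP", "NoLRP"), fitted = TRUE),
    class = "xdawn_filter")
  a <- matrix(rnorm(6 * 20), 6, 20)
  b <- matrix(rnorm(6 * 20), 6, 20)
  expect_identical(apply_xdawn(a, fit), a[1:4, ])
  expect_equal(apply_xdawn(0 * a, fit), matrix(0, 4, 20))
  lhs <- apply_xdawn(2 * a - 3 * b, fit)
  rhs <- 2 * apply_xdawn(a, fit) - 3 * apply_xdawn(b, fit)
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(apply_xdawn(a[1:3, ], fit), "channel count")
})

test_that("features are the last 4 samples per pseudo-channel, channel-major", {
  ps <- matrix(seq_len(80), 4, 20, byrow = TRUE)
  f <- extract_features(ps)
  expect_length(f, 16)
  expect_equal(f[1:4], ps[1, 17:20])
  expect_equal(f[5:8], ps[2, 17:20])
  expect_equal(extract_features(matrix(0, 4, 20)), rep(0, 16))
})

test_that("the fitted normalizer gives zero-mean unit-variance training features", {
  set.seed(8)
  feats <- matrix(rnorm(200 * 16, 5, 3), 200, 16)
  nz <- fit_feature_normalizer(feats)
  z <- lrpdetect:::apply_normalizer(feats, nz)
  expect_lt(max(abs(colMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 2, stats::var) - 1)), 1e-9)
  # zero-SD feature flagged and mapped with SD 1
  feats[, 3] <- 2
  nz2 <- fit_feature_normalizer(feats)
  expect_equal(unname(nz2$zero_sd_features), 3L)
  expect_equal(unname(nz2$sd[3]), 1)
})

test_that("the feature pipeline is deterministic end to end", {
  trials <- small_trial_windows()
  w <- trials[[1]]
  labels <- rep(c("LRP", "NoLRP"), length.out = nrow(w))
  f1 <- fit_xdawn(w$data, labels)
  f2 <- fit_xdawn(w$data, labels)
  expect_identical(f1$weights, f2$weights)
  v1 <- extract_features(apply_xdawn(w$data[[81]], f1))
  v2 <- extract_features(apply_xdawn(w$data[[81]], f2))
  expect_identical(v1, v2)
})
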