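# Training-set assembly, the L1-SVM solver, grid search, Platt calibration
# and window prediction.

test_that("assembly selects exactly the five designated windows per trial", {
  ts <- make_toy_training(n_trials = 80)
  expect_equal(sum(ts$label == "LRP"), 160)
  expect_equal(sum(ts$label == "NoLRP"), 240)
  lrp_starts <- sort(unique(ts$start[ts$label == "LRP"]))
  expect_equal(lrp_starts, c(-1.10, -1.00), tolerance = 1e-9)
  no_starts <- sort(unique(ts$start[ts$label == "NoLRP"]))
  expect_equal(no_starts, c(-3.50, -3.25, -3.05), tolerance = 1e-9)
  expect_error(assemble_training_set(list()), "empty")
  # assembly from real preprocessed trials: 5 instances each
  trials <- small_trial_windows()
  ts2 <- assemble_training_set(trials)
  expect_equal(nrow(ts2), 5 * length(trials))
  expect_equal(as.integer(table(ts2$label)[c("LRP", "NoLRP")]),
               c(2L, 3L) * length(trials))
})

test_that("the L1-SVM solves the primal: optimality and sparsity", {
  set.seed(10)
  n <- 120
  x <- matrix(rnorm(n * 8), n, 8)
  y <- ifelse(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.3) > 0, "LRP", "NoLRP")
  C_used <- 0.05
  fit <- fit_l1_svm(x, y, C = C_used)
  yv <- ifelse(y == "LRP", 1, -1)
  s <- ifelse(yv > 0, 2, 1)
  obj <- function(w, b) {
    h <- pmax(0, 1 - yv * (drop(x %*% w) + b))
    sum(abs(w)) + C_used * sum(s * h^2)
  }
  o0 <- obj(fit$w, fit$b)
  expect_equal(o0, fit$objective, tolerance = 1e-8)
  # no random perturbation improves the objective: convex optimum
  set.seed(11)
  for (i in 1:50) {
    dw <- rnorm(8, 0, 0.01)
    db <- rnorm(1, 0, 0.01)
    expect_gte(obj(fit$w + dw, fit$b + db), o0 - 1e-8)
  }
  # independent general-purpose optimizer cannot do better
  par0 <- rep(0, 9)
  opt <- optim(par0, function(p) obj(p[1:8], p[9]), method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  expect_lte(o0, opt$value + 1e-6)
  # irrelevant noisy features are mostly driven to exactly zero
  expect_gt(sum(fit$w[3:8] == 0), 0)
})

test_that("stronger LRP class weight never lowers the training TPR", {
  set.seed(12)
  n <- 100
  x <- matrix(rnorm(n * 4), n, 4)
  y <- ifelse(x[, 1] + rnorm(n, 0, 1.2) > 0, "LRP", "NoLRP")
  tprs <- vapply(c(1, 2, 4, 8), function(wl) {
    f <- fit_l1_svm(x, y, C = 0.3, class_weights = c(NoLRP = 1, LRP = wl))
    pred <- predict(f, x) > 0
    mean(pred[y == "LRP"])
  }, numeric(1))
  expect_true(all(diff(tprs) >= -1e-9))
})

test_that("grid search uses the 7-decade grid and separable data trains to BA 1", {
  expect_equal(lrpdetect:::SVM_C_GRID, 10^(-6:0))
  ts <- make_toy_training(n_trials = 10)
  model <- train_model(ts, seed = 3)
  expect_true(model$C %in% 10^(-6:0))
  expect_equal(nrow(model$cv), 7)
  # training-set predictions are perfect on separable toy data
  feats <- t(vapply(ts$data, function(w)
    extract_features(apply_xdawn(w, model$xdawn)), numeric(16)))
  z <- lrpdetect:::apply_normalizer(feats, model$normalizer)
  pred <- ifelse(drop(z %*% model$svm$w) + model$svm$b > 0, "LRP", "NoLRP")
  acc <- balanced_accuracy(pred, ts$label)
  expect_equal(acc$ba, 1.0)
  # reproducibility: same seed, same choice and weights
  model2 <- train_model(ts, seed = 3)
  expect_identical(model2$C, model$C)
  expect_identical(model2$svm$w, model$svm$w)
  expect_error(train_model(ts[ts$label == "LRP", ]), "both classes")
  expect_error(train_model(ts[1:8, ]), "fold")
})

test_that("Platt probabilities increase with the decision value", {
  set.seed(14)
  scores <- c(rnorm(60, -1), rnorm(60, 1))
  y <- rep(c("NoLRP", "LRP"), each = 60)
  cal <- fit_platt(scores, y)
  sweep <- seq(-3, 3, by = 0.1)
  p <- lrpdetect:::platt_probability(cal, sweep)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
})

test_that("prediction uses a strict 0.5 threshold and checks dimensions", {
  ts <- make_toy_training(n_trials = 10)
  model <- train_model(ts, seed = 3)
  # force a boundary calibration: sigmoid(A*0 + B) = 0.5
  model$platt <- structure(list(A = 1, B = 0), class = "platt_calibration")
  model$svm$w <- rep(0, 16)
  model$svm$b <- 0
  model$normalizer$mean <- rep(0, 16)
  model$normalizer$sd <- rep(1, 16)
  at_boundary <- predict_window(model, rep(0, 16))
  expect_equal(at_boundary$probability, 0.5)
  expect_equal(at_boundary$label, "NoLRP") # strictly greater than 0.5
  model$svm$b <- 0.08 # probability just above 0.5
  above <- predict_window(model, rep(0, 16))
  expect_gt(above$probability, 0.5)
  expect_equal(above$label, "LRP")
  expect_error(predict_window(model, rep(0, 7)), "dimensionality")
})

test_that("linear predictions are equivariant under feature permutation", {
  ts <- make_toy_training(n_trials = 10)
  model <- train_model(ts, seed = 5)
  v <- rnorm(16)
  perm <- sample(16)
  m2 <- model
  m2$svm$w <- model$svm$w[perm]
  m2$normalizer$mean <- model$normalizer$mean[perm]
  m2$normalizer$sd <- model$normalizer$sd[perm]
  expect_equal(predict_window(m2, v[perm])$probability,
               predict_window(model, v)$probability, tolerance = 1e-12)
})

test_that("models survive a serialization round trip", {
  ts <- make_toy_training(n_trials = 10)
  model <- train_model(ts, seed = 8)
  path <- tempfile(fileext = ".rds")
  saveRDS(model, path)
  loaded <- readRDS(path)
  v <- rnorm(16)
  expect_identical(predict_window(loaded, v), predict_window(model, v))
  w <- small_trial_windows()[[1]]
  m_real <- train_model(assemble_training_set(small_trial_windows()),
                        seed = 2)
  p1 <- predict_trial(m_real, w)
  saveRDS(m_real, path)
  p2 <- predict_trial(readRDS(path), w)
  expect_identical(p1, p2)
})
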