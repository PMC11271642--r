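# Training-set assembly (the five designated windows per trial), complexity
# grid search with 5-fold cross-validation, final L1-SVM fit with 1:2 class
# weights, and Platt calibration: the movement-intention detector.

LRP_TRAIN_STARTS <- c(-1.10, -1.00)
NOLRP_TRAIN_STARTS <- c(-3.05, -3.25, -3.50)
SVM_C_GRID <- 10^(-6:0)

#' Assemble the labeled training set from trial windows
#'
#' Per valid trial, exactly five designated windows become training
#' instances: `[-1.10, -0.10]` and `[-1.00, 0.00]` s as the LRP (movement
#' intention) class, and `[-3.05, -2.05]`, `[-3.25, -2.25]`,
#' `[-3.50, -2.50]` s as the NoLRP (resting) class.
#'
#' @param trials A list of per-trial `sliding_windows` tibbles (81 windows,
#'   preprocessed stage).
#' @return A `training_set` tibble: `trial`, `window`, `start`, `end`,
#'   `label`, `data` (list-column of preprocessed matrices).
#' @export
assemble_training_set <- function(trials) {
  trials <- purrr::compact(trials)
  if (length(trials) == 0) {
    stop("empty trial list: no training trials available", call. = FALSE)
  }
  near <- function(x, targets) {
    vapply(x, function(v) any(abs(v - targets) < 1e-9), logical(1))
  }
  pick <- function(windows, trial_id) {
    sel_lrp <- near(windows$start, LRP_TRAIN_STARTS)
    sel_no <- near(windows$start, NOLRP_TRAIN_STARTS)
    if (sum(sel_lrp) != length(LRP_TRAIN_STARTS) ||
        sum(sel_no) != length(NOLRP_TRAIN_STARTS)) {
      stop("trial windows do not contain the designated training windows",
           call. = FALSE)
    }
    out <- windows[sel_lrp | sel_no, c("window", "start", "end", "data")]
    out$label <- ifelse(near(out$start, LRP_TRAIN_STARTS), "LRP", "NoLRP")
    dplyr::mutate(out, trial = trial_id, .before = 1)
  }
  out <- purrr::map_dfr(seq_along(trials), function(i) pick(trials[[i]], i))
  class(out) <- c("training_set", class(out))
  out
}

# deterministic stratified fold assignment
cv_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Train the movement-intention detector
#'
#' Fits the full detector on an assembled training set: xDAWN spatial
#' filters and the Gaussian feature normalizer are estimated on these
#' training windows only; the SVM complexity `C` is chosen by stratified
#' 5-fold cross-validation over the 7-value grid `10^-6 ... 10^0`
#' (selection metric: balanced accuracy; ties resolved toward the smaller
#' `C`); the final L1-SVM is refit on the whole training set with class
#' weights NoLRP:LRP = 1:2; and Platt's sigmoid is fitted on the training
#' decision values.
#'
#' @param training_set A [assemble_training_set()] tibble.
#' @param montage Optional [get_montage()] recorded as model provenance.
#' @param seed Integer seed for the cross-validation fold assignment.
#' @param grid Complexity grid (default `10^(-6:0)`).
#' @param n_folds Cross-validation folds (default 5).
#' @param n_filters xDAWN pseudo-channels (default 4).
#' @param calibration `"train"` (default) fits Platt on the full training
#'   scores; `"cv"` fits it on 3-fold held-out scores.
#' @param fold_id Optional tag naming the outer train fold this model was
#'   fitted on (train/test hygiene bookkeeping).
#' @return An `intent_model`.
#' @export
train_model <- function(training_set, montage = NULL, seed = 1,
                        grid = SVM_C_GRID, n_folds = 5, n_filters = 4,
                        calibration = c("train", "cv"), fold_id = NULL) {
  calibration <- match.arg(calibration)
  labels <- training_set$label
  if (length(unique(labels)) < 2) {
    stop("both classes must be present in the training set", call. = FALSE)
  }
  if (min(table(labels)) < n_folds) {
    stop("too few instances per class for ", n_folds, "-fold ",
         "cross-validation", call. = FALSE)
  }
  xdawn <- fit_xdawn(training_set$data, labels, n_filters = n_filters)
  raw_feats <- t(vapply(training_set$data, function(w)
    extract_features(apply_xdawn(w, xdawn)), numeric(n_filters * 4)))
  normalizer <- fit_feature_normalizer(raw_feats)
  feats <- apply_normalizer(raw_feats, normalizer)
  fold <- cv_folds(labels, n_folds, seed)
  cv <- purrr::map_dfr(grid, function(C) {
    scores <- purrr::map_dfr(seq_len(n_folds), function(f) {
      svm <- fit_l1_svm(feats[fold != f, , drop = FALSE], labels[fold != f],
                        C = C)
      pred <- ifelse(predict(svm, feats[fold == f, , drop = FALSE]) > 0,
                     "LRP", "NoLRP")
      truth <- labels[fold == f]
      tibble::tibble(
        tpr = mean(pred[truth == "LRP"] == "LRP"),
        tnr = mean(pred[truth == "NoLRP"] == "NoLRP")
      )
    })
    tibble::tibble(C = C, cv_ba = mean((scores$tpr + scores$tnr) / 2))
  })
  best <- which.max(cv$cv_ba + 1e-12 * rev(seq_len(nrow(cv)))) # ties -> small C
  chosen_C <- cv$C[best]
  svm <- fit_l1_svm(feats, labels, C = chosen_C)
  platt_scores <- if (calibration == "train") {
    predict(svm, feats)
  } else {
    cal_fold <- cv_folds(labels, 3, seed + 1)
    out <- numeric(length(labels))
    for (f in 1:3) {
      m <- fit_l1_svm(feats[cal_fold != f, , drop = FALSE],
                      labels[cal_fold != f], C = chosen_C)
      out[cal_fold == f] <- predict(m, feats[cal_fold == f, , drop = FALSE])
    }
    out
  }
  platt <- fit_platt(platt_scores, labels)
  structure(
    list(montage = montage, xdawn = xdawn, normalizer = normalizer,
         svm = svm, C = chosen_C, cv = cv, platt = platt,
         threshold = 0.5, seed = seed, fold_id = fold_id),
    class = "intent_model"
  )
}

#' @export
print.intent_model <- function(x, ...) {
  cat("<intent_model>\n")
  if (!is.null(x$montage)) {
    cat(sprintf("  montage %s:%d\n", x$montage$scheme, x$montage$n_channels))
  }
  cat(sprintf("  C = %g (5-fold CV balanced accuracy %.3f)\n",
              x$C, max(x$cv$cv_ba)))
  cat(sprintf("  %d/%d nonzero SVM weights; Platt A=%.3f B=%.3f\n",
              sum(x$svm$w != 0), length(x$svm$w), x$platt$A, x$platt$B))
  invisible(x)
}

#' Predict the LRP probability of a single window
#'
#' @param model A fitted `intent_model`.
#' @param feature_vector Length-16 feature vector as produced by
#'   [extract_features()] without a normalizer (the model applies its own
#'   training normalizer).
#' @return A one-row tibble: `score`, `probability`, `label` (LRP iff
#'   probability strictly exceeds 0.5).
#' @export
predict_window <- function(model, feature_vector) {
  if (length(feature_vector) != length(model$svm$w)) {
    stop("feature vector has wrong dimensionality: expected ",
         length(model$svm$w), call. = FALSE)
  }
  z <- (feature_vector - model$normalizer$mean) / model$normalizer$sd
  score <- sum(z * model$svm$w) + model$svm$b
  prob <- platt_probability(model$platt, score)
  tibble::tibble(
    score = score, probability = prob,
    label = ifelse(prob > model$threshold, "LRP", "NoLRP")
  )
}

#' Predict every sliding window of a trial
#'
#' Emulates online operation: the 81 windows of a trial are pushed through
#' the model's xDAWN filters, feature extraction, normalizer, SVM and Platt
#' calibration.
#'
#' @param model A fitted `intent_model`.
#' @param windows A preprocessed `sliding_windows` tibble (81 rows).
#' @return A `trial_predictions` tibble: `window`, `start`, `end`, `score`,
#'   `probability`, `label`.
#' @export
predict_trial <- function(model, windows) {
  feats <- t(vapply(windows$data, function(w)
    extract_features(apply_xdawn(w, model$xdawn)),
    numeric(ncol(model$xdawn$weights) * 4)))
  z <- apply_normalizer(feats, model$normalizer)
  score <- drop(z %*% model$svm$w) + model$svm$b
  prob <- platt_probability(model$platt, score)
  out <- dplyr::bind_cols(
    windows[c("window", "start", "end")],
    tibble::tibble(score = score, probability = prob,
                   label = ifelse(prob > model$threshold, "LRP", "NoLRP"))
  )
  class(out) <- c("trial_predictions", class(out))
  out
}
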