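# Emulated online evaluation: leave-one-set-out splits, change-point
# relabeling of the prediction sequence into per-window ground truth, pooled
# balanced accuracy, and the three train-test transfer conditions.

CONDITION_TASKS <- list(
  A = c(train = "unilateral", test = "unilateral"),
  B = c(train = "bilateral", test = "bilateral"),
  C = c(train = "bilateral", test = "unilateral")
)

# boundaries of the relabeling range, as window start times
RELABEL_RANGE_STARTS <- c(-2.00, -1.00)

#' Leave-one-set-out train/test splits
#'
#' Each of the three measurement sets serves exactly once as the test set
#' while the other two train the model.
#'
#' @param n_sets Number of sets (must be 3).
#' @return A tibble with columns `test_set` and `train_sets` (list-column).
#' @export
#' @examples
#' make_splits()
make_splits <- function(n_sets = 3) {
  if (n_sets != 3) {
    stop("leave-one-set-out validation requires exactly 3 sets",
         call. = FALSE)
  }
  tibble::tibble(
    test_set = seq_len(n_sets),
    train_sets = purrr::map(seq_len(n_sets), function(s)
      setdiff(seq_len(n_sets), s))
  )
}

# fast core of the relabeling rule on a logical LRP-prediction vector over
# the canonical 81-window grid; returns the logical LRP truth vector
relabel_core <- function(pred_lrp, range_idx) {
  lo <- range_idx[1]
  hi <- range_idx[2]
  n_range <- hi - lo + 1
  no_lrp <- !pred_lrp[lo:hi]
  run3 <- no_lrp[1:(n_range - 2)] & no_lrp[2:(n_range - 1)] &
    no_lrp[3:n_range]
  truth_range <- if (any(run3)) {
    # first run found scanning backward from the latest window; the change
    # point sits immediately later than that run
    run_end <- max(which(run3)) + 2
    c(rep(FALSE, run_end), rep(TRUE, n_range - run_end))
  } else {
    rep(TRUE, n_range) # no change point: long movement-planning phase
  }
  truth <- c(rep(FALSE, lo - 1), truth_range)
  truth[hi] <- TRUE # fixed boundary label of window [-1, 0]
  truth
}

#' Relabel a trial's prediction sequence into per-window ground truth
#'
#' Implements the change-point relabeling protocol: windows before the
#' window starting at -2.00 s are fixed NoLRP, the window `[-1.00, 0.00]` s
#' is fixed LRP, and within the range between those two boundary windows
#' the NoLRP-to-LRP change point is located from the predicted labels
#' themselves. Scanning backward in time from window `[-1.00, 0.00]`, the
#' first run of three consecutive NoLRP predictions wholly inside the range
#' places the change point immediately after (later than) the run: all
#' windows before the point become NoLRP truth, all windows past it LRP
#' truth. If no such run exists, every window in the range is labeled LRP
#' (a long movement-planning phase). Fixed boundary labels are applied
#' last. The result is always a single monotone NoLRP-to-LRP step.
#'
#' @param predictions A `trial_predictions` tibble over the canonical
#'   81-window grid (or any tibble with `window`, `start`, `label`).
#' @return A `ground_truth_labels` tibble: `window`, `start`, `truth`
#'   (`"LRP"`/`"NoLRP"`), with the change point (start time of the first
#'   in-range LRP-truth window, or `NA`) as attribute `change_point`.
#' @export
relabel_trial <- function(predictions) {
  grid <- window_grid()
  if (nrow(predictions) != nrow(grid) ||
      max(abs(predictions$start - grid$start)) > 1e-9) {
    stop("predictions are not on the canonical 81-window grid",
         call. = FALSE)
  }
  range_idx <- c(which(abs(grid$start - RELABEL_RANGE_STARTS[1]) < 1e-9),
                 which(abs(grid$start - RELABEL_RANGE_STARTS[2]) < 1e-9))
  truth <- relabel_core(predictions$label == "LRP", range_idx)
  # reported as the start time of the first in-range LRP-truth window (the
  # fixed [-1, 0] window guarantees at least one)
  in_range_lrp <- which(truth[range_idx[1]:range_idx[2]]) + range_idx[1] - 1
  cp <- grid$start[min(in_range_lrp)]
  out <- tibble::tibble(
    window = grid$window, start = grid$start,
    truth = ifelse(truth, "LRP", "NoLRP")
  )
  attr(out, "change_point") <- cp
  class(out) <- c("ground_truth_labels", class(out))
  out
}

#' Balanced accuracy of window predictions
#'
#' With LRP as the positive class: TPR = correctly predicted LRP windows /
#' LRP-truth windows, TNR likewise for NoLRP, and BA = (TPR + TNR) / 2,
#' computed pooled over all supplied windows.
#'
#' @param predictions Predicted labels (`"LRP"`/`"NoLRP"`, or logical LRP
#'   indicators).
#' @param truths True labels, same length and coding.
#' @return A one-row tibble: `ba`, `tpr`, `tnr`, `n`.
#' @export
#' @examples
#' balanced_accuracy(c("LRP", "NoLRP", "LRP"), c("LRP", "NoLRP", "NoLRP"))
balanced_accuracy <- function(predictions, truths) {
  as_lrp <- function(x) if (is.logical(x)) x else as.character(x) == "LRP"
  p <- as_lrp(predictions)
  t <- as_lrp(truths)
  if (length(p) != length(t)) {
    stop("predictions and truths must have equal length", call. = FALSE)
  }
  if (!any(t) || all(t)) {
    stop("a class is absent in the truth labels: rate undefined",
         call. = FALSE)
  }
  tpr <- mean(p[t])
  tnr <- mean(!p[!t])
  tibble::tibble(ba = (tpr + tnr) / 2, tpr = tpr, tnr = tnr, n = length(p))
}

## ---- condition runner --------------------------------------------------

# per subject-task: annotate onsets and preprocess all 81 windows of every
# usable trial under the montage; returns list(sets = list of list(trials)),
# each trial a preprocessed sliding_windows tibble
prepare_subject_task <- function(std, montage, grid = window_grid()) {
  std <- annotate_dataset(std)
  sets <- purrr::map(seq_along(std$sets), function(s) {
    rec <- apply_montage(std$sets[[s]]$recording, montage)
    marks <- std$onsets[std$onsets$set_index == s & std$onsets$used, ]
    trials <- purrr::compact(purrr::map(marks$onset, function(on) {
      w <- suppressWarnings(cut_windows(rec, on, grid))
      if (is.null(w)) NULL else preprocess_window(w)
    }))
    trials
  })
  list(sets = sets, onsets = std$onsets)
}

subject_task_block <- function(x, subject, task) {
  if (inherits(x, "lrp_study")) {
    x$subjects[[subject]][[task]]
  } else {
    generate_subject_task(x, subject, task)
  }
}

#' Run one train-test transfer condition
#'
#' Conditions: `"A"` unilateral-unilateral (no transfer), `"B"`
#' bilateral-bilateral (no transfer), `"C"` bilateral-unilateral
#' (cross-task transfer). For every subject and every leave-one-set-out
#' split, a detector is trained on the condition's training task and
#' training sets and evaluated on the held-out set of the test task: all
#' 81 windows of each test trial are predicted, relabeled into ground
#' truth, and scored by pooled balanced accuracy. All fitted artifacts
#' (xDAWN filters, feature normalizer, SVM, Platt calibration) come from
#' training data only.
#'
#' @param x A [study_config()] (subject blocks are generated on the fly,
#'   which keeps memory flat) or a materialized `lrp_study`.
#' @param condition `"A"`, `"B"` or `"C"`.
#' @param montage A [get_montage()] result or `"scheme:n"` string (default
#'   `"custom:32"`).
#' @param seed Integer seed for fold assignment substreams.
#' @return A `condition_report` tibble with one row per subject and split:
#'   `subject`, `condition`, `montage`, `test_set`, `ba`, `tpr`, `tnr`,
#'   `n_train_trials`, `n_test_trials`, `chosen_C`.
#' @export
run_condition <- function(x, condition = c("A", "B", "C"),
                          montage = "custom:32", seed = 1) {
  condition <- match.arg(condition)
  if (is.character(montage)) {
    montage <- get_montage(montage)
  }
  config <- if (inherits(x, "lrp_study")) x$config else x
  tasks <- CONDITION_TASKS[[condition]]
  results <- purrr::map_dfr(seq_len(config$n_subjects), function(subj) {
    train_prep <- prepare_subject_task(
      subject_task_block(x, subj, tasks[["train"]]), montage)
    test_prep <- if (tasks[["train"]] == tasks[["test"]]) {
      train_prep
    } else {
      prepare_subject_task(
        subject_task_block(x, subj, tasks[["test"]]), montage)
    }
    splits <- make_splits(config$n_sets_per_task)
    purrr::map_dfr(seq_len(nrow(splits)), function(k) {
      train_sets <- splits$train_sets[[k]]
      test_set <- splits$test_set[k]
      train_trials <- purrr::flatten(train_prep$sets[train_sets])
      ts <- assemble_training_set(train_trials)
      model <- train_model(
        ts, montage = montage,
        seed = derive_seed(seed, subj, match(condition, c("A", "B", "C")),
                           test_set),
        fold_id = sprintf("subj%d_%s_test%d", subj, condition, test_set))
      test_trials <- test_prep$sets[[test_set]]
      pred <- character(0)
      truth <- character(0)
      for (tr in test_trials) {
        p <- predict_trial(model, tr)
        g <- relabel_trial(p)
        pred <- c(pred, p$label)
        truth <- c(truth, g$truth)
      }
      acc <- balanced_accuracy(pred, truth)
      tibble::tibble(
        subject = subj, condition = condition,
        montage = sprintf("%s:%d", montage$scheme, montage$n_channels),
        test_set = test_set, ba = acc$ba, tpr = acc$tpr, tnr = acc$tnr,
        n_train_trials = length(train_trials),
        n_test_trials = length(test_trials),
        chosen_C = model$C
      )
    })
  })
  attr(results, "condition") <- condition
  attr(results, "montage") <- montage
  class(results) <- c("condition_report", class(results))
  results
}

#' Aggregate a condition report
#'
#' @param report A `condition_report` (or several row-bound together).
#' @return A tibble with mean and SD of the balanced accuracy (and rates)
#'   per condition and montage.
#' @export
summarize_conditions <- function(report) {
  dplyr::summarise(
    dplyr::group_by(report, .data$condition, .data$montage),
    n_folds = dplyr::n(),
    mean_ba = mean(.data$ba), sd_ba = stats::sd(.data$ba),
    mean_tpr = mean(.data$tpr), mean_tnr = mean(.data$tnr),
    .groups = "drop"
  )
}
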