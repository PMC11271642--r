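# Shared fixtures: tiny study configurations, toy windows/features, and the
# independently coded relabeling oracle. Everything is generated in code.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixture_env[[name]])) {
    .fixture_env[[name]] <- make()
  }
  .fixture_env[[name]]
}

tiny_config <- function(...) {
  study_config(n_subjects = 1, n_sets_per_task = 3, n_trials_per_set = 4,
               n_channels = 8, ...)
}

# a prepared single subject-task block with estimated onsets (cached)
small_annotated <- function() {
  fixture("small_annotated", function() {
    annotate_dataset(generate_subject_task(tiny_config(), 1, "unilateral"))
  })
}

# preprocessed 81-window tibbles for the trials of one set (cached)
small_trial_windows <- function() {
  fixture("small_trial_windows", function() {
    std <- small_annotated()
    rec <- std$sets[[1]]$recording
    marks <- std$onsets[std$onsets$set_index == 1 & std$onsets$used, ]
    lapply(marks$onset, function(on)
      preprocess_window(cut_windows(rec, on)))
  })
}

# toy "preprocessed windows" with a deterministic class-dependent pattern in
# the trailing samples; linearly separable by construction
make_toy_training <- function(n_trials = 12, n_channels = 6, sep = 4,
                              noise = 0.3, seed = 42) {
  set.seed(seed)
  grid <- window_grid()
  starts <- c(-1.10, -1.00, -3.05, -3.25, -3.50)
  labels <- c("LRP", "LRP", "NoLRP", "NoLRP", "NoLRP")
  rows <- list()
  for (tr in seq_len(n_trials)) {
    for (j in seq_along(starts)) {
      w <- matrix(rnorm(n_channels * 20, 0, noise), n_channels, 20)
      if (labels[j] == "LRP") {
        w[1, 17:20] <- w[1, 17:20] + sep
      }
      k <- which(abs(grid$start - starts[j]) < 1e-9)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial = tr, window = grid$window[k], start = grid$start[k],
        end = grid$end[k], label = labels[j], data = list(w))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("training_set", class(out))
  out
}

# independently coded brute-force relabeling: an explicit backward counter
# scan over the in-range predictions, per the written rule
relabel_oracle <- function(pred_labels) {
  stopifnot(length(pred_labels) == 81)
  lo <- 61
  hi <- 81
  is_no <- pred_labels == "NoLRP"
  run_end <- NA
  count <- 0
  for (i in hi:lo) {
    if (is_no[i]) {
      count <- count + 1
      if (count == 3) {
        run_end <- i + 2 # run occupies i, i+1, i+2
        break
      }
    } else {
      count <- 0
    }
  }
  truth <- rep("NoLRP", 81)
  if (is.na(run_end)) {
    truth[lo:hi] <- "LRP"
  } else if (run_end < hi) {
    truth[(run_end + 1):hi] <- "LRP"
  }
  truth[hi] <- "LRP" # fixed boundary window
  truth[1:(lo - 1)] <- "NoLRP"
  truth
}

# canonical predictions tibble from a logical LRP vector
predictions_from_logical <- function(lrp) {
  g <- window_grid()
  out <- dplyr::mutate(g, score = 0, probability = as.numeric(lrp),
                       label = ifelse(lrp, "LRP", "NoLRP"))
  class(out) <- c("trial_predictions", class(out))
  out
}
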