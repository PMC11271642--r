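# Assembly of full synthetic study datasets: per subject and task, a set of
# continuous EEG recordings with events, per-trial motion traces, and the
# ground-truth trial table.

TASK_LEVELS <- c("unilateral", "bilateral")
POST_MOVEMENT_S <- 0.9 # return-to-switch time appended after each reach

task_code <- function(task) match(task, TASK_LEVELS)

# trial layout of one measurement set; all randomness from `seed`
draw_set_layout <- function(config, seed) {
  set.seed(seed)
  n <- config$n_trials_per_set
  invalid <- stats::runif(n) < config$invalid_rate
  rest <- ifelse(invalid,
                 stats::runif(n, config$rest_duration_min - 1,
                              config$rest_duration_min - 0.1),
                 stats::runif(n, config$rest_duration_min,
                              config$rest_duration_min + 2))
  trial_len <- rest + config$reach_duration + POST_MOVEMENT_S
  start <- cumsum(c(0, trial_len[-n]))
  tibble::tibble(
    trial_index = seq_len(n),
    trial_start = start,
    rest_duration = rest,
    true_onset = start + rest,
    trial_end = start + trial_len,
    valid = !invalid
  )
}

generate_set_eeg <- function(config, task, layout, seed) {
  set.seed(seed)
  fs <- config$eeg_rate
  n <- round(max(layout$trial_end) * fs)
  channels <- config_channels(config)
  x <- synth_noise(length(channels), n, fs, config$noise_sd,
                   config$noise_model, config$noise_channel_cor)
  pattern <- unname(lrp_spatial_pattern(channels, task))
  for (onset in layout$true_onset) {
    onset_sample <- round(onset * fs) + 1
    lo <- max(1, onset_sample - round((config$lrp_duration + 0.1) * fs))
    hi <- min(n, onset_sample + round(0.4 * fs))
    course <- lrp_time_course(config, hi - lo + 1, onset_sample - lo + 1)
    x[, lo:hi] <- x[, lo:hi] + outer(pattern, course)
  }
  side <- if (task == "unilateral") "right" else "both"
  events <- dplyr::bind_rows(
    tibble::tibble(time = layout$trial_start, kind = "switch_press",
                   side = side),
    tibble::tibble(time = layout$true_onset + config$mech_delay,
                   kind = "switch_release", side = side),
    tibble::tibble(time = layout$true_onset + config$reach_duration,
                   kind = "button_press", side = side),
    tibble::tibble(time = layout$true_onset[!layout$valid],
                   kind = "invalid_trial", side = side)
  )
  events <- dplyr::arrange(events, .data$time)
  eeg_recording(x, channels, fs, events)
}

generate_set_motion <- function(config, task, layout, seed) {
  set.seed(seed)
  hands <- if (task == "unilateral") "right" else c("left", "right")
  purrr::map(seq_len(nrow(layout)), function(i) {
    row <- layout[i, ]
    traces <- purrr::map(hands, function(h) {
      tr <- synthesize_trial_motion(
        config, true_onset = row$rest_duration, hand = h,
        duration = row$trial_end - row$trial_start
      )
      # shift to absolute set time
      tr$time <- tr$time + row$trial_start
      tr$switch_release <- tr$switch_release + row$trial_start
      tr
    })
    stats::setNames(traces, hands)
  })
}

#' Generate one subject-task block of the synthetic study
#'
#' Produces, for a single subject and task, `n_sets_per_task` measurement
#' sets each holding a continuous EEG recording with its event table, one
#' motion trace per trial and hand, and the ground-truth trial table. All
#' randomness derives deterministically from `config$seed`, the subject
#' index, the task and the set index, so any block can be regenerated in
#' isolation.
#'
#' @param config A [study_config()].
#' @param subject Subject index (1-based).
#' @param task `"unilateral"` or `"bilateral"`.
#' @param include_eeg,include_motion Set `FALSE` to skip generating the
#'   corresponding component (the trial layout is unaffected).
#' @return A `subject_task_data` object: list with `subject`, `task`,
#'   `sets` (per set: `recording`, `motion`, `ground_truth`) and a pooled
#'   `ground_truth` tibble.
#' @export
generate_subject_task <- function(config, subject, task,
                                  include_eeg = TRUE,
                                  include_motion = TRUE) {
  stopifnot(task %in% TASK_LEVELS)
  sets <- purrr::map(seq_len(config$n_sets_per_task), function(s) {
    layout <- draw_set_layout(
      config, derive_seed(config$seed, subject, task_code(task), s, 1))
    rec <- if (include_eeg) {
      generate_set_eeg(
        config, task, layout,
        derive_seed(config$seed, subject, task_code(task), s, 2))
    }
    mot <- if (include_motion) {
      generate_set_motion(
        config, task, layout,
        derive_seed(config$seed, subject, task_code(task), s, 3))
    }
    gt <- dplyr::mutate(layout, subject = subject, task = task,
                        set_index = s, .before = 1)
    list(recording = rec, motion = mot, ground_truth = gt)
  })
  structure(
    list(subject = subject, task = task, sets = sets,
         ground_truth = dplyr::bind_rows(purrr::map(sets, "ground_truth")),
         config = config),
    class = "subject_task_data"
  )
}

#' @export
print.subject_task_data <- function(x, ...) {
  cat(sprintf("<subject_task_data> subject %d, %s task: %d set(s), %d trial(s)\n",
              x$subject, x$task, length(x$sets), nrow(x$ground_truth)))
  invisible(x)
}

#' Generate a full synthetic study dataset
#'
#' Materializes every subject-task block of the configured study. With the
#' default configuration (8 subjects, 2 tasks, 3 sets of 40 trials, 64
#' channels at 500 Hz) the result occupies several gigabytes; for large
#' sweeps prefer streaming over [generate_subject_task()] blocks, which is
#' what [run_condition()] and [run_experiment()] do internally when given a
#' `study_config`.
#'
#' Identical configurations (including `seed`) yield identical datasets.
#'
#' @param config A [study_config()].
#' @return An `lrp_study` object: list with `config` and
#'   `subjects[[subject]][[task]]` blocks from [generate_subject_task()].
#' @export
#' @examples
#' cfg <- study_config(n_subjects = 1, n_sets_per_task = 1,
#'                     n_trials_per_set = 2, n_channels = 8)
#' study <- generate_dataset(cfg)
#' nrow(study$subjects[[1]]$unilateral$ground_truth)
generate_dataset <- function(config) {
  if (!inherits(config, "study_config")) {
    stop("`config` must be a study_config", call. = FALSE)
  }
  subjects <- purrr::map(seq_len(config$n_subjects), function(subj) {
    stats::setNames(
      purrr::map(TASK_LEVELS, function(tk)
        generate_subject_task(config, subj, tk)),
      TASK_LEVELS
    )
  })
  structure(list(config = config, subjects = subjects), class = "lrp_study")
}

#' @export
print.lrp_study <- function(x, ...) {
  cat(sprintf("<lrp_study> %d subject(s) x 2 tasks x %d set(s) x %d trial(s)\n",
              x$config$n_subjects, x$config$n_sets_per_task,
              x$config$n_trials_per_set))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' EEG goes to per-set TSV matrices, events/ground truth/motion to TSV
#' tables, and the configuration and seed to a JSON manifest, under
#' `dir/subject-<s>/<task>/`.
#'
#' @param study An `lrp_study` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (subj in seq_along(study$subjects)) {
    for (task in names(study$subjects[[subj]])) {
      std <- study$subjects[[subj]][[task]]
      base <- file.path(dir, sprintf("subject-%02d", subj), task)
      dir.create(base, recursive = TRUE, showWarnings = FALSE)
      for (s in seq_along(std$sets)) {
        set <- std$sets[[s]]
        stem <- file.path(base, sprintf("set-%d", s))
        if (!is.null(set$recording)) {
          write_recording_tsv(set$recording, stem)
        }
        if (!is.null(set$motion)) {
          mot <- purrr::map_dfr(seq_along(set$motion), function(i) {
            dplyr::mutate(
              dplyr::bind_rows(purrr::map(set$motion[[i]], as_tibble.motion_trace)),
              trial_index = i, .before = 1)
          })
          readr::write_tsv(mot, paste0(stem, "_motion.tsv"))
        }
      }
      readr::write_tsv(std$ground_truth,
                       file.path(base, "ground_truth.tsv"))
    }
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(generator = "lrpdetect synthetic study",
         config = unclass(study$config)),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a motion TSV written by [write_dataset()]
#'
#' @param path TSV with columns `time`, `x`, `y`, `z`, `hand` and optionally
#'   `trial_index`.
#' @param rate Sampling rate in Hz.
#' @param switch_release Release time in seconds for the trace.
#' @return A [motion_trace()] (first trial/hand if several are present).
#' @export
read_motion_tsv <- function(path, rate, switch_release) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if ("trial_index" %in% names(df)) {
    df <- df[df$trial_index == df$trial_index[1], ]
  }
  if ("hand" %in% names(df)) {
    hand <- df$hand[1]
    df <- df[df$hand == hand, ]
  } else {
    hand <- "right"
  }
  motion_trace(as.matrix(df[c("x", "y", "z")]), df$time, rate,
               switch_release, hand)
}
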