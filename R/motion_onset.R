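# Estimation of the physical movement onset from hand-marker kinematics:
# distance to rest times max-normalized low-pass-filtered velocity, scanned
# backward from the hand-switch release for the first sub-threshold sample.

#' Kinematic profile of a motion trace
#'
#' Re-zeroes the marker positions by the mean over the initial
#' `rest_window` seconds, computes the Euclidean distance to the rest
#' position, the per-sample velocity of that distance (first difference,
#' first sample 0) low-pass filtered at 4 Hz (4th-order Butterworth,
#' zero-phase by default) and normalized to the trial maximum, and their
#' elementwise product.
#'
#' @param trace A [motion_trace()].
#' @param rest_window Seconds of initial rest used to define the rest
#'   position (default 1).
#' @param zero_phase Apply the velocity filter forward-backward (default
#'   `TRUE`); `FALSE` uses a single causal pass.
#' @return A `kinematic_profile` tibble with columns `time`, `distance`
#'   (mm), `velocity` (dimensionless, max 1) and `product` (mm), carrying
#'   the trace's `rate` and `switch_release` as attributes.
#' @export
kinematic_profile <- function(trace, rest_window = 1, zero_phase = TRUE) {
  fs <- trace$rate
  n_rest <- round(rest_window * fs)
  if (nrow(trace$positions) <= n_rest) {
    stop("trace shorter than `rest_window`", call. = FALSE)
  }
  rest_mean <- colMeans(trace$positions[seq_len(n_rest), , drop = FALSE])
  p0 <- sweep(trace$positions, 2, rest_mean)
  distance <- sqrt(rowSums(p0^2))
  velocity_raw <- c(0, diff(distance))
  bf <- signal::butter(4, 4 / (fs / 2), type = "low")
  velocity_f <- if (zero_phase) {
    signal::filtfilt(bf, velocity_raw)
  } else {
    as.numeric(signal::filter(bf, velocity_raw))
  }
  vmax <- max(velocity_f)
  if (!is.finite(vmax) || vmax <= 0) {
    stop("degenerate trial: no movement in trace (zero velocity)",
         call. = FALSE)
  }
  velocity <- velocity_f / vmax
  out <- tibble::tibble(
    time = trace$time,
    distance = distance,
    velocity = velocity,
    product = distance * velocity
  )
  attr(out, "rate") <- fs
  attr(out, "switch_release") <- trace$switch_release
  class(out) <- c("kinematic_profile", class(out))
  out
}

#' Estimate the physical movement onset from a kinematic profile
#'
#' Starting at the hand-switch release and scanning backward in time, the
#' onset is the latest sample at or before the release whose
#' distance-times-velocity product magnitude falls below `threshold` mm.
#'
#' @param profile A [kinematic_profile()].
#' @param switch_release Search start in seconds (defaults to the release
#'   time recorded on the profile).
#' @param threshold Product magnitude threshold in mm (default 0.6, the
#'   spatial resolution of a calibrated motion-capture system).
#' @return An `onset_estimate`: list with `onset_time`, `threshold` and
#'   `search_start`.
#' @export
estimate_onset <- function(profile,
                           switch_release = attr(profile, "switch_release"),
                           threshold = 0.6) {
  if (is.null(switch_release) ||
      switch_release < profile$time[1] ||
      switch_release > profile$time[nrow(profile)]) {
    stop("`switch_release` must lie within the profile", call. = FALSE)
  }
  candidates <- which(profile$time <= switch_release &
                        abs(profile$product) < threshold)
  if (length(candidates) == 0) {
    stop("onset-not-found: no sample below threshold before the switch ",
         "release (trial flagged invalid)", call. = FALSE)
  }
  structure(
    list(onset_time = profile$time[max(candidates)],
         threshold = threshold,
         search_start = switch_release),
    class = "onset_estimate"
  )
}

#' @export
print.onset_estimate <- function(x, ...) {
  cat(sprintf("<onset_estimate> %.3f s (search start %.3f s, threshold %g mm)\n",
              x$onset_time, x$search_start, x$threshold))
  invisible(x)
}

#' Annotate a subject-task block with estimated movement onsets
#'
#' Runs the kinematic onset estimator over every trial of a
#' [generate_subject_task()] block and merges the resulting onset markers
#' into each set's EEG event stream. For bilateral trials the left-hand
#' trace is used (the arm whose abilities label the data); unilateral trials
#' use the moved right hand. Trials whose resting period violates the 5 s
#' minimum, and trials where the backward search fails, are excluded.
#'
#' @param x A `subject_task_data` block with motion traces.
#' @param threshold Product threshold in mm passed to [estimate_onset()].
#' @param rest_window Rest window in seconds for [kinematic_profile()].
#' @return `x` with an added `onsets` tibble (one row per trial: estimated
#'   `onset`, `true_onset`, `valid`, `used` and `reason`) and
#'   `movement_onset` events appended to each set recording.
#' @export
annotate_dataset <- function(x, threshold = 0.6, rest_window = 1) {
  if (!inherits(x, "subject_task_data")) {
    stop("`x` must be a subject_task_data block", call. = FALSE)
  }
  hand <- if (x$task == "bilateral") "left" else "right"
  onsets <- purrr::map_dfr(seq_along(x$sets), function(s) {
    set <- x$sets[[s]]
    gt <- set$ground_truth
    if (length(set$motion) != nrow(gt)) {
      stop("alignment error: trial count mismatch between events and traces",
           call. = FALSE)
    }
    purrr::map_dfr(seq_len(nrow(gt)), function(i) {
      row <- gt[i, ]
      trace <- set$motion[[i]][[hand]]
      if (is.null(trace)) {
        stop("alignment error: no ", hand, "-hand trace for trial ", i,
             call. = FALSE)
      }
      est <- tryCatch(
        estimate_onset(kinematic_profile(trace, rest_window),
                       threshold = threshold),
        error = function(e) NULL
      )
      reason <- if (!row$valid) {
        "rest_under_minimum"
      } else if (is.null(est)) {
        "onset_not_found"
      } else {
        NA_character_
      }
      tibble::tibble(
        subject = row$subject, task = row$task, set_index = s,
        trial_index = row$trial_index,
        onset = if (is.null(est)) NA_real_ else est$onset_time,
        true_onset = row$true_onset,
        valid = row$valid,
        used = is.na(reason),
        reason = reason
      )
    })
  })
  x$onsets <- onsets
  for (s in seq_along(x$sets)) {
    if (is.null(x$sets[[s]]$recording)) next
    marks <- onsets[onsets$set_index == s & onsets$used, ]
    side <- if (x$task == "unilateral") "right" else "both"
    ev <- dplyr::arrange(
      dplyr::bind_rows(
        x$sets[[s]]$recording$events,
        tibble::tibble(time = marks$onset, kind = "movement_onset",
                       side = side)
      ),
      .data$time
    )
    x$sets[[s]]$recording$events <- ev
  }
  x
}
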