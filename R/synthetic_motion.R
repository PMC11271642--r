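# Synthetic hand-marker trajectories: minimum-jerk reach toward the button
# preceded by a fast lift-off of the hand from its switch.

# classic minimum-jerk position profile, 0 -> 1 over tau in [0, 1]
minimum_jerk <- function(tau) {
  p <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  p[tau <= 0] <- 0
  p[tau >= 1] <- 1
  p
}

# lift-off transient: the hand must physically leave the spring-loaded
# switch for it to release ~30 ms after movement start, so displacement
# rises fast (25 mm within 50 ms) and is reabsorbed into the reach path
LIFTOFF_AMP_MM <- 25
LIFTOFF_RISE_S <- 0.05
LIFTOFF_DECAY_S <- 0.25

#' Construct a motion trace
#'
#' @param positions Numeric time x 3 matrix of marker positions in mm
#'   (columns x, y, z).
#' @param time Time stamps in seconds (same length as rows of `positions`).
#' @param rate Sampling rate in Hz.
#' @param switch_release Hand-switch release time in seconds; must lie
#'   within the trace.
#' @param hand `"left"` or `"right"`.
#' @return A `motion_trace` object.
#' @export
motion_trace <- function(positions, time, rate, switch_release,
                         hand = "right") {
  if (!is.matrix(positions) || ncol(positions) != 3 ||
      any(!is.finite(positions))) {
    stop("`positions` must be a finite time x 3 matrix", call. = FALSE)
  }
  if (nrow(positions) != length(time)) {
    stop("`time` must match rows of `positions`", call. = FALSE)
  }
  if (switch_release < time[1] || switch_release > time[length(time)]) {
    stop("`switch_release` must lie within the trace", call. = FALSE)
  }
  colnames(positions) <- c("x", "y", "z")
  structure(
    list(positions = positions, time = time, rate = rate,
         switch_release = switch_release, hand = hand),
    class = "motion_trace"
  )
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %s hand, %d samples @ %g Hz, release at %.3f s\n",
              x$hand, nrow(x$positions), x$rate, x$switch_release))
  invisible(x)
}

#' Convert a motion trace to a tibble
#' @param x A [motion_trace()].
#' @param ... Unused.
#' @return A tibble with columns `time`, `x`, `y`, `z`, `hand`.
#' @export
as_tibble.motion_trace <- function(x, ...) {
  pos <- x$positions
  hand <- x$hand
  time <- x$time
  tibble::tibble(time = time,
                 x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
                 hand = hand)
}

#' Synthesize a single-trial hand-marker trajectory
#'
#' The marker rests at the hand switch (with Gaussian jitter of
#' `config$jitter_sd` mm), then moves along a minimum-jerk path to the reach
#' target over `config$reach_duration` seconds starting at `true_onset`,
#' with a fast transient lift-off from the switch superimposed so that the
#' switch mechanically releases `config$mech_delay` seconds after the true
#' onset.
#'
#' @inheritParams synthesize_trial_eeg
#' @param true_onset Movement onset in seconds relative to trace start; must
#'   lie inside the trace.
#' @param hand `"left"` or `"right"`.
#' @param duration Total trace duration in seconds.
#' @return A [motion_trace()] whose `switch_release` equals
#'   `true_onset + config$mech_delay`.
#' @export
synthesize_trial_motion <- function(config, true_onset, hand = "right",
                                    seed = NULL,
                                    duration = true_onset + 1.5) {
  if (true_onset <= 0 || true_onset >= duration) {
    stop("generation error: `true_onset` must lie inside the trace",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  fs <- config$motion_rate
  time <- seq(0, duration - 1 / fs, by = 1 / fs)
  tau <- (time - true_onset) / config$reach_duration
  p <- minimum_jerk(tau)
  pos <- cbind(x = config$reach_target[1] * p,
               y = config$reach_target[2] * p,
               z = config$reach_target[3] * p)
  lift <- LIFTOFF_AMP_MM *
    minimum_jerk((time - true_onset) / LIFTOFF_RISE_S) *
    (1 - minimum_jerk((time - true_onset - LIFTOFF_RISE_S) / LIFTOFF_DECAY_S))
  pos[, "z"] <- pos[, "z"] + lift
  if (config$jitter_sd > 0) {
    pos <- pos + matrix(stats::rnorm(length(pos), 0, config$jitter_sd),
                        ncol = 3)
  }
  motion_trace(pos, time, fs,
               switch_release = true_onset + config$mech_delay,
               hand = hand)
}
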