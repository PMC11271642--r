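#' Configuration of a synthetic reach-to-target study
#'
#' Describes a self-paced reaching study: `n_subjects` subjects each perform a
#' unilateral (right-arm) and a bilateral task, organised in
#' `n_sets_per_task` measurement sets of `n_trials_per_set` self-initiated
#' trials. Every trial is a resting period of at least `rest_duration_min`
#' seconds followed by a reach; a slow negative readiness potential ramps up
#' over the motor cortex during the last `lrp_duration` seconds before the
#' physical movement onset, reaching `lrp_amplitude` microvolts at the onset.
#'
#' @param n_subjects Number of subjects (default 8).
#' @param n_sets_per_task Measurement sets per task (default 3).
#' @param n_trials_per_set Trials per set (default 40).
#' @param eeg_rate EEG sampling rate in Hz (default 500).
#' @param motion_rate Motion-capture sampling rate in Hz (default 500).
#' @param n_channels Number of EEG channels (default 64, the full cap layout;
#'   smaller counts keep the channels nearest to C1 so that motor cortex
#'   coverage is preserved in reduced simulations).
#' @param rest_duration_min Minimum valid resting period in seconds
#'   (default 5); trials whose drawn rest is shorter are flagged invalid.
#' @param lrp_amplitude Peak amplitude of the pre-movement negativity in
#'   microvolts (default -6; negative values are negativities).
#' @param lrp_duration Ramp duration of the pre-movement negativity in
#'   seconds (default 1).
#' @param noise_sd Standard deviation of the background EEG noise in
#'   microvolts (default 10).
#' @param noise_model `"pink"` (1/f-shaped, default) or `"white"` background
#'   noise.
#' @param noise_channel_cor Pairwise correlation of noise between channels
#'   (default 0.2).
#' @param lrp_shape `"linear"` ramp (default) or `"half_cosine"` rise.
#' @param invalid_rate Fraction of trials whose resting period violates the
#'   5 s minimum (default 0.02), to exercise invalid-trial handling.
#' @param mech_delay Mechanical delay between true movement onset and the
#'   hand-switch release event, in seconds (default 0.03).
#' @param reach_duration Duration of the minimum-jerk reach in seconds
#'   (default 0.6).
#' @param reach_target Reach displacement from the rest position in mm,
#'   length-3 `(x, y, z)` (default `c(0, 300, 250)`: 30 cm forward, 25 cm up).
#' @param jitter_sd Standard deviation of marker position jitter in mm
#'   (default 0.2).
#' @param seed Integer seed from which all per-subject/per-task random
#'   substreams are derived (default 1).
#' @return A validated `study_config` object (a named list).
#' @export
#' @examples
#' cfg <- study_config(n_subjects = 1, n_trials_per_set = 5)
#' cfg$n_trials_per_set
study_config <- function(n_subjects = 8,
                         n_sets_per_task = 3,
                         n_trials_per_set = 40,
                         eeg_rate = 500,
                         motion_rate = 500,
                         n_channels = 64,
                         rest_duration_min = 5,
                         lrp_amplitude = -6,
                         lrp_duration = 1.0,
                         noise_sd = 10,
                         noise_model = c("pink", "white"),
                         noise_channel_cor = 0.2,
                         lrp_shape = c("linear", "half_cosine"),
                         invalid_rate = 0.02,
                         mech_delay = 0.03,
                         reach_duration = 0.6,
                         reach_target = c(0, 300, 250),
                         jitter_sd = 0.2,
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  lrp_shape <- match.arg(lrp_shape)
  check_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
        x != round(x)) {
      stop("invalid study configuration: `", name,
           "` must be a count >= 1", call. = FALSE)
    }
  }
  check_pos <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      stop("invalid study configuration: `", name,
           "` must be a positive number", call. = FALSE)
    }
  }
  check_count(n_subjects, "n_subjects")
  check_count(n_sets_per_task, "n_sets_per_task")
  check_count(n_trials_per_set, "n_trials_per_set")
  check_count(n_channels, "n_channels")
  check_pos(eeg_rate, "eeg_rate")
  check_pos(motion_rate, "motion_rate")
  check_pos(lrp_duration, "lrp_duration")
  if (!is.numeric(rest_duration_min) || rest_duration_min < 5) {
    stop("invalid study configuration: `rest_duration_min` must be >= 5 s",
         call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("invalid study configuration: `noise_sd` must be >= 0",
         call. = FALSE)
  }
  if (!is.numeric(invalid_rate) || invalid_rate < 0 || invalid_rate >= 1) {
    stop("invalid study configuration: `invalid_rate` must be in [0, 1)",
         call. = FALSE)
  }
  if (n_channels > 64) {
    stop("invalid study configuration: `n_channels` must be <= 64",
         call. = FALSE)
  }
  if (length(reach_target) != 3 || !all(is.finite(reach_target))) {
    stop("invalid study configuration: `reach_target` must be 3 finite mm",
         call. = FALSE)
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_sets_per_task = as.integer(n_sets_per_task),
      n_trials_per_set = as.integer(n_trials_per_set),
      eeg_rate = eeg_rate,
      motion_rate = motion_rate,
      n_channels = as.integer(n_channels),
      rest_duration_min = rest_duration_min,
      lrp_amplitude = lrp_amplitude,
      lrp_duration = lrp_duration,
      noise_sd = noise_sd,
      noise_model = noise_model,
      noise_channel_cor = noise_channel_cor,
      lrp_shape = lrp_shape,
      invalid_rate = invalid_rate,
      mech_delay = mech_delay,
      reach_duration = reach_duration,
      reach_target = as.numeric(reach_target),
      jitter_sd = jitter_sd,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  %d subject(s), 2 tasks x %d set(s) x %d trial(s)\n",
              x$n_subjects, x$n_sets_per_task, x$n_trials_per_set))
  cat(sprintf("  EEG %g Hz, %d channels; motion %g Hz\n",
              x$eeg_rate, x$n_channels, x$motion_rate))
  cat(sprintf("  LRP %g uV over %g s (%s); noise %g uV (%s, rho=%g)\n",
              x$lrp_amplitude, x$lrp_duration, x$lrp_shape,
              x$noise_sd, x$noise_model, x$noise_channel_cor))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

# channels used for a configured channel count: full layout for 64, otherwise
# the n channels nearest to C1 on the schematic grid (keeps motor coverage)
config_channels <- function(config) {
  layout <- acticap64_layout()
  if (config$n_channels == 64L) {
    return(layout)
  }
  pos <- channel_positions(layout)
  c1 <- pos[pos$channel == "C1", ]
  d <- sqrt((pos$x - c1$x)^2 + (pos$y - c1$y)^2)
  layout[order(d, seq_along(d))][seq_len(config$n_channels)]
}

# deterministic substream seed derivation; stays below 2^31
derive_seed <- function(seed, ...) {
  parts <- c(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    h <- (h * 7919 + as.double(p) * 104729 + 12345) %% 2147483647
  }
  as.integer(h)
}
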