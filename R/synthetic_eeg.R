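# Synthetic EEG: correlated 1/f background noise plus a lateralized slow
# negativity injected before each movement onset.

# spatial falloff (schematic grid units) of the injected readiness potential
LRP_SPATIAL_SIGMA <- 1.2

#' Scalp weighting of the simulated readiness potential
#'
#' Gaussian falloff on the schematic electrode plane, centred over the left
#' motor cortex at C1 for unilateral right-arm movements and symmetric about
#' the midline (equal lobes at C1 and C2) for bilateral movements. The
#' maximum weight is 1.
#'
#' @param channels Channel labels to weight.
#' @param task `"unilateral"` or `"bilateral"`.
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
#' @examples
#' w <- lrp_spatial_pattern(c("C1", "C2", "C3", "Oz"), "bilateral")
#' w[["C1"]] == w[["C2"]]
lrp_spatial_pattern <- function(channels, task = c("unilateral", "bilateral")) {
  task <- match.arg(task)
  pos <- channel_positions(channels)
  gauss_at <- function(cx, cy) {
    exp(-((pos$x - cx)^2 + (pos$y - cy)^2) / (2 * LRP_SPATIAL_SIGMA^2))
  }
  w <- if (task == "unilateral") {
    gauss_at(-1, 0) # C1
  } else {
    (gauss_at(-1, 0) + gauss_at(1, 0)) / 2 # C1 + C2, midline-symmetric
  }
  w <- w / max(w)
  stats::setNames(w, channels)
}

# temporal course of the negativity, sampled on the EEG grid, relative to
# onset: zero before (onset - lrp_duration), |amplitude| at the onset sample,
# then linear return to baseline over `decay` seconds
lrp_time_course <- function(config, n_samples, onset_sample,
                            decay = 0.3) {
  fs <- config$eeg_rate
  t_rel <- (seq_len(n_samples) - onset_sample) / fs
  ramp <- numeric(n_samples)
  rising <- t_rel > -config$lrp_duration & t_rel <= 0
  frac <- 1 + t_rel[rising] / config$lrp_duration
  ramp[rising] <- if (config$lrp_shape == "linear") {
    frac
  } else {
    (1 - cos(pi * frac)) / 2
  }
  falling <- t_rel > 0 & t_rel < decay
  ramp[falling] <- 1 - t_rel[falling] / decay
  config$lrp_amplitude * ramp
}

# 1/f-shaped (or white) Gaussian noise, channels x samples, channel pairwise
# correlation rho via a shared component; uses the current RNG state
synth_noise <- function(n_channels, n_samples, rate, sd,
                        model = "pink", rho = 0.2) {
  if (sd == 0) {
    return(matrix(0, n_channels, n_samples))
  }
  # pad to a 5-smooth length so the mixed-radix FFT stays O(n log n)
  m <- stats::nextn(n_samples, c(2, 3, 5))
  shape <- if (model == "pink") {
    f <- c(0, seq_len(m - 1)) * rate / m
    f <- pmin(f, rate - f) # two-sided bin frequencies
    a <- 1 / sqrt(pmax(f, 0.5))
    a[1] <- 0 # no DC
    a / sqrt(mean(a^2))
  } else {
    NULL
  }
  one_series <- function() {
    if (is.null(shape)) {
      return(stats::rnorm(n_samples))
    }
    w <- stats::rnorm(m)
    Re(stats::fft(stats::fft(w) * shape, inverse = TRUE))[seq_len(n_samples)] / m
  }
  shared <- one_series()
  out <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    out[ch, ] <- sd * (sqrt(rho) * shared + sqrt(1 - rho) * one_series())
  }
  out
}

#' Synthesize single-trial EEG around a known movement onset
#'
#' Returns a channels x time segment equal to background noise plus the
#' task-specific spatial pattern times the temporal ramp of the simulated
#' readiness potential, peaking at `true_onset`.
#'
#' @param config A [study_config()].
#' @param task `"unilateral"` or `"bilateral"`.
#' @param true_onset Onset time in seconds relative to segment start; must
#'   leave at least `config$rest_duration_min` of pre-onset samples.
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @param duration Total segment duration in seconds (default
#'   `true_onset + 1.5`).
#' @return Channels x time numeric matrix (microvolts) with channel names as
#'   row names and attributes `rate` and `onset`.
#' @export
synthesize_trial_eeg <- function(config, task, true_onset, seed = NULL,
                                 duration = true_onset + 1.5) {
  if (true_onset < config$rest_duration_min) {
    stop("generation error: `true_onset` too close to segment start ",
         "(needs the resting period before it)", call. = FALSE)
  }
  if (!is.null(seed)) {
    set.seed(seed)
  }
  fs <- config$eeg_rate
  n <- round(duration * fs)
  channels <- config_channels(config)
  x <- synth_noise(length(channels), n, fs, config$noise_sd,
                   config$noise_model, config$noise_channel_cor)
  pattern <- lrp_spatial_pattern(channels, task)
  onset_sample <- round(true_onset * fs) + 1
  x <- x + outer(unname(pattern),
                 lrp_time_course(config, n, onset_sample))
  rownames(x) <- channels
  attr(x, "rate") <- fs
  attr(x, "onset") <- true_onset
  x
}
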