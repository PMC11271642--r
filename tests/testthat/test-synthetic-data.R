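# Synthetic study generator: cardinalities, determinism, spatial pattern
# lateralization, ramp recovery, signal-free stationarity.

test_that("study layout has the designed cardinalities and valid events", {
  cfg <- study_config(n_subjects = 2, n_sets_per_task = 3,
                      n_trials_per_set = 5, n_channels = 8)
  std <- generate_subject_task(cfg, 1, "unilateral")
  expect_length(std$sets, 3)
  expect_equal(nrow(std$ground_truth), 15)
  for (set in std$sets) {
    ev <- set$recording$events
    expect_false(is.unsorted(ev$time))
    gt <- set$ground_truth
    # every trial: one switch_release and one button_press, release first
    expect_equal(sum(ev$kind == "switch_release"), nrow(gt))
    expect_equal(sum(ev$kind == "button_press"), nrow(gt))
    rel <- sort(ev$time[ev$kind == "switch_release"])
    btn <- sort(ev$time[ev$kind == "button_press"])
    expect_true(all(rel < btn))
    # onsets strictly inside the recording; invalid iff rest under minimum
    expect_true(all(gt$true_onset > 0 & gt$true_onset < set$recording$duration))
    expect_equal(gt$valid, gt$rest_duration >= cfg$rest_duration_min)
  }
})

test_that("identical configurations generate identical datasets", {
  cfg <- tiny_config(seed = 7)
  a <- generate_subject_task(cfg, 1, "bilateral")
  b <- generate_subject_task(cfg, 1, "bilateral")
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$sets[[2]]$recording$data, b$sets[[2]]$recording$data)
  expect_identical(a$sets[[1]]$motion[[1]]$left$positions,
                   b$sets[[1]]$motion[[1]]$left$positions)
  # a different seed changes the data
  c <- generate_subject_task(study_config(n_subjects = 1,
                                          n_sets_per_task = 3,
                                          n_trials_per_set = 4,
                                          n_channels = 8, seed = 8),
                             1, "bilateral")
  expect_false(identical(a$sets[[1]]$recording$data,
                         c$sets[[1]]$recording$data))
})

test_that("spatial pattern is lateralized for unilateral, symmetric for bilateral", {
  ch <- c("C1", "C2", "C3", "C4", "Cz", "Oz")
  uni <- lrp_spatial_pattern(ch, "unilateral")
  bil <- lrp_spatial_pattern(ch, "bilateral")
  expect_gt(abs(uni[["C1"]]), abs(uni[["C2"]]))
  expect_gt(abs(uni[["C3"]]), abs(uni[["C4"]]))
  expect_equal(bil[["C1"]], bil[["C2"]])
  expect_equal(bil[["C3"]], bil[["C4"]])
  expect_equal(max(uni), 1)
  # far-away occipital channel carries much less of the pattern
  expect_lt(bil[["Oz"]], 0.05)
})

test_that("averaging many trials at C1 recovers the injected ramp shape", {
  cfg <- study_config(n_subjects = 1, n_trials_per_set = 1, n_channels = 8,
                      noise_sd = 2, seed = 11)
  fs <- cfg$eeg_rate
  onset <- 5.5
  n_trials <- 500
  n <- round((onset + 0.5) * fs)
  acc <- numeric(n)
  for (i in seq_len(n_trials)) {
    x <- synthesize_trial_eeg(cfg, "unilateral", onset, seed = 1000 + i,
                              duration = onset + 0.5)
    acc <- acc + x["C1", ]
  }
  avg <- acc / n_trials
  onset_sample <- round(onset * fs) + 1
  expected <- lrpdetect:::lrp_time_course(cfg, n, onset_sample)
  expect_lt(max(abs(avg - expected)), 0.1 * abs(cfg$lrp_amplitude))
})

test_that("zero-amplitude configuration leaves no onset-locked deflection", {
  cfg <- study_config(n_subjects = 1, n_trials_per_set = 1, n_channels = 8,
                      lrp_amplitude = 0, seed = 3)
  fs <- cfg$eeg_rate
  onset <- 5.2
  n_trials <- 120
  pre <- numeric(n_trials)
  pre_var <- post_var <- numeric(n_trials)
  for (i in seq_len(n_trials)) {
    x <- synthesize_trial_eeg(cfg, "unilateral", onset, seed = 2000 + i,
                              duration = onset + 0.5)
    o <- round(onset * fs)
    pre[i] <- mean(x["C1", (o - 99):o])
    pre_var[i] <- stats::var(x["C1", (o - 99):o])
    post_var[i] <- stats::var(x["C1", (o + 1):(o + 100)])
  }
  # mean pre-onset amplitude below 3 SEM of the noise-only average
  sem <- stats::sd(pre) / sqrt(n_trials)
  expect_lt(abs(mean(pre)), 3 * sem)
  # covariance-stationary: no window-position effect above noise
  expect_gt(mean(pre_var) / mean(post_var), 0.9)
  expect_lt(mean(pre_var) / mean(post_var), 1.1)
})

test_that("invalid-trial rate matches the configured violation probability", {
  cfg <- study_config(n_subjects = 1, n_sets_per_task = 3,
                      n_trials_per_set = 60, n_channels = 8,
                      invalid_rate = 0.1, seed = 5)
  std <- generate_subject_task(cfg, 1, "unilateral", include_eeg = FALSE,
                               include_motion = FALSE)
  n <- nrow(std$ground_truth)
  k <- sum(!std$ground_truth$valid)
  ci <- stats::binom.test(k, n, 0.1)$conf.int
  expect_true(0.1 >= ci[1] && 0.1 <= ci[2])
})

test_that("onset too close to the segment start is a generation error", {
  cfg <- tiny_config()
  expect_error(synthesize_trial_eeg(cfg, "unilateral", true_onset = 2),
               "too close")
  expect_error(study_config(n_subjects = 0), "n_subjects")
  expect_error(study_config(rest_duration_min = 3), "rest_duration_min")
})

test_that("synthetic motion reaches the target and releases the switch on time", {
  cfg <- study_config(n_subjects = 1, jitter_sd = 0, n_channels = 8)
  tr <- synthesize_trial_motion(cfg, true_onset = 6, duration = 7.4)
  # exactly constant before onset when jitter is off
  pre <- tr$positions[tr$time < 6, ]
  expect_equal(max(abs(pre)), 0)
  # final Euclidean displacement ~ sqrt(300^2 + 250^2) = 390.5 mm
  final <- sqrt(sum(tr$positions[nrow(tr$positions), ]^2))
  expect_equal(final, sqrt(300^2 + 250^2), tolerance = 1e-6)
  expect_equal(tr$switch_release - 6, cfg$mech_delay)
})
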