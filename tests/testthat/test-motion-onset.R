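# Kinematic onset estimation: profile construction, backward threshold
# search, recovery of generator ground truth, equivariance properties.

make_trace <- function(positions, rate = 500, release = NULL) {
  n <- nrow(positions)
  time <- (seq_len(n) - 1) / rate
  if (is.null(release)) release <- time[n]
  motion_trace(positions, time, rate, release)
}

test_that("stationary trace yields near-zero distance and a degenerate error", {
  set.seed(1)
  jit <- 0.1
  pos <- matrix(rnorm(3000 * 3, 0, jit), ncol = 3)
  prof <- kinematic_profile(make_trace(pos))
  expect_lt(max(prof$distance), 3 * jit * sqrt(3) + 3 * jit)
  # strictly zero movement -> no velocity maximum to normalize
  expect_error(kinematic_profile(make_trace(matrix(0, 1000, 3))),
               "degenerate")
})

test_that("velocity is max-normalized to exactly 1 on a moving trial", {
  cfg <- study_config(n_subjects = 1, n_channels = 8)
  tr <- synthesize_trial_motion(cfg, true_onset = 6, seed = 2,
                                duration = 7.4)
  prof <- kinematic_profile(tr)
  expect_equal(max(prof$velocity), 1)
  expect_true(all(prof$velocity <= 1))
})

test_that("constant-slope distance gives constant filtered velocity (gain 1)", {
  # ramp moving 1 mm/sample along y after 1 s of rest
  n <- 2500
  y <- c(rep(0, 500), seq_len(n - 500))
  pos <- cbind(0, y, 0)
  prof <- kinematic_profile(make_trace(pos))
  mid <- 1500:2300
  # unfiltered velocity is exactly the constant slope
  raw <- c(0, diff(prof$distance))
  expect_equal(unname(stats::median(raw[mid])), 1)
  expect_lt(max(abs(raw[mid] - 1)), 1e-9)
  # after the filter transient the filtered velocity converges to the same
  # constant (constant-input gain 1): flat to < 1% relative error
  expect_lt(max(abs(prof$velocity[mid] / prof$velocity[2000] - 1)), 0.01)
})

test_that("onset estimator recovers generator ground truth within 20 ms", {
  cfg <- study_config(n_subjects = 1, n_channels = 8)
  errs <- vapply(1:30, function(i) {
    tr <- synthesize_trial_motion(cfg, true_onset = 6, seed = 100 + i,
                                  duration = 7.4)
    est <- estimate_onset(kinematic_profile(tr))
    est$onset_time - 6
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.020), 0.95)
  # onset never after the switch release
  expect_true(all(errs <= cfg$mech_delay + 1e-9))
})

test_that("zero product before the search start places the onset at the start", {
  n <- 2000
  time <- (seq_len(n) - 1) / 500
  # move only in the last 200 samples; release placed before any movement
  y <- c(rep(0, 1800), cumsum(rep(2, 200)))
  prof <- kinematic_profile(make_trace(cbind(0, y, 0), release = 2.0))
  est <- estimate_onset(prof, switch_release = 2.0)
  expect_equal(est$onset_time, 2.0)
  expect_equal(est$threshold, 0.6) # default search criterion
})

test_that("estimate errors when no sample falls below threshold", {
  # distance large and growing everywhere: product never below threshold
  y <- 50 + cumsum(rep(2, 1500))
  tr <- make_trace(cbind(0, y, 0))
  prof <- kinematic_profile(tr, rest_window = 0.5)
  prof$product <- abs(prof$product) + 1 # force all samples above threshold
  expect_error(estimate_onset(prof, switch_release = 2.5), "onset-not-found")
})

test_that("estimates are shift-equivariant and robust to position scaling", {
  cfg <- study_config(n_subjects = 1, n_channels = 8)
  tr <- synthesize_trial_motion(cfg, true_onset = 6, seed = 9,
                                duration = 7.6)
  est <- estimate_onset(kinematic_profile(tr))
  # time shift by exactly 0.2 s
  tr2 <- tr
  tr2$time <- tr$time + 0.2
  tr2$switch_release <- tr$switch_release + 0.2
  est2 <- estimate_onset(kinematic_profile(tr2))
  expect_equal(est2$onset_time, est$onset_time + 0.2, tolerance = 1e-9)
  # doubling all positions moves the estimate at most 3 samples
  tr3 <- tr
  tr3$positions <- tr$positions * 2
  est3 <- estimate_onset(kinematic_profile(tr3))
  expect_lte(abs(est3$onset_time - est$onset_time), 3 / tr$rate + 1e-9)
})

test_that("annotation uses the left hand for bilateral tasks and excludes bad trials", {
  cfg <- study_config(n_subjects = 1, n_sets_per_task = 1,
                      n_trials_per_set = 6, n_channels = 8,
                      invalid_rate = 0.4, seed = 21)
  std <- annotate_dataset(generate_subject_task(cfg, 1, "bilateral"))
  gt <- std$ground_truth
  expect_equal(sum(std$onsets$used), sum(gt$valid))
  expect_true(all(is.na(std$onsets$reason[std$onsets$used])))
  # onset markers merged into the event stream, one per used trial
  ev <- std$sets[[1]]$recording$events
  expect_equal(sum(ev$kind == "movement_onset"), sum(gt$valid))
  # estimates came from the left-hand trace: re-estimate directly
  i <- which(std$onsets$used)[1]
  tr <- std$sets[[1]]$motion[[std$onsets$trial_index[i]]]$left
  est <- estimate_onset(kinematic_profile(tr))
  expect_equal(std$onsets$onset[i], est$onset_time)
  # every onset precedes its trial's switch release
  rel <- gt$true_onset + cfg$mech_delay
  expect_true(all(std$onsets$onset[std$onsets$used] <=
                    rel[std$onsets$used] + 1e-9))
})
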