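# lrpdetect

Asynchronous detection of movement intention from multichannel EEG via the
lateralized readiness potential (LRP), with cross-task transfer from
bilateral to unilateral arm movements.

## The problem

Exoskeleton-supported stroke rehabilitation needs a classifier that
recognizes, from ongoing EEG, when a patient intends to move the affected
arm — without spending scarce therapy time on dedicated calibration
sessions. One way around calibration is cross-task transfer: while the
patient exercises *bilateral* mirrored movements (the robot mirrors the
unaffected arm onto the affected one), EEG can be recorded and labeled
automatically from the unaffected arm's movement onsets. A detector trained
on that data is then transferred to predict *unilateral* movement
intentions of the affected arm. Because the LRP — a slow negative potential
over the motor cortex contralateral to the moved limb — precedes the
physical movement onset by up to a second, a sliding-window classifier over
the pre-movement EEG can detect the intention before the movement.

`lrpdetect` implements that pipeline end to end, exercisable entirely on
synthetic data with known ground truth:

* **Synthetic study generator** — seeded datasets shaped like a self-paced
  reaching study: 8 subjects × 2 tasks (unilateral/bilateral) × 3 sets ×
  40 trials; 64-channel EEG at 500 Hz with correlated 1/f noise and a
  lateralized negative ramp injected before each movement onset;
  minimum-jerk hand-marker trajectories; hand-switch/button event tables.
* **Kinematic onset labeling** — the physical movement onset per trial is
  the latest pre-release sample where (distance to rest) × (max-normalized
  low-pass-filtered velocity) falls below 0.6 mm, searched backward from
  the hand-switch release.
* **Montages** — nested left-hemisphere selections centred on C1
  (32/21/16/8/4 channels) and standard extended 10-20 constellations
  (32/21/16).
* **Feature pipeline** — 81 sliding windows of 1 s, stepped 0.05 s, over
  [-5, 0] s relative to onset; per window: channel-wise standardization →
  decimation 500 → 20 Hz → FFT band-pass 0.1–4 Hz → xDAWN spatial
  filtering to 4 pseudo-channels → last 4 samples (0.2 s) as 16 features →
  Gaussian feature normalization.
* **Classifier** — L1-regularized linear SVM (squared hinge), complexity
  chosen by 5-fold CV over `10^-6 … 10^0`, class weights NoLRP:LRP = 1:2,
  Platt-calibrated probabilities, intention declared when p > 0.5.
* **Evaluation** — leave-one-set-out folds; per test trial all 81 windows
  are predicted, per-window ground truth is derived by change-point
  relabeling (backward scan for three consecutive NoLRP predictions inside
  [-2, 0] s, with fixed boundary labels), and performance is the balanced
  accuracy BA = (TPR + TNR)/2 pooled over windows. Transfer conditions:
  A unilateral→unilateral, B bilateral→bilateral, C bilateral→unilateral.

## Worked example

A one-subject miniature of the cross-task transfer condition (~1 min):

```r
library(lrpdetect)

cfg <- study_config(n_subjects = 1, n_trials_per_set = 10, seed = 42)

# onsets estimated from the synthetic hand-marker kinematics
std <- annotate_dataset(generate_subject_task(cfg, 1, "unilateral"))
head(std$onsets[c("trial_index", "onset", "true_onset", "valid")], 3)
#>   trial_index onset true_onset valid
#> 1           1  6.16       6.15 TRUE
#> 2           2 14.7       14.6  TRUE
#> 3           3 22.3       22.3  TRUE

# train on bilateral movements, test on unilateral (condition C)
report <- run_condition(cfg, condition = "C", montage = "custom:8",
                        seed = 42)
summarize_conditions(report)
#>   condition  montage n_folds mean_ba  sd_ba mean_tpr mean_tnr
#> 1         C custom:8       3   0.648 0.0411    0.569    0.728
```

Each fold row reports the balanced accuracy of emulated online detection
on the held-out set: `onset` is the kinematic estimate of the physical
movement onset (here within ~15 ms of the generator's ground truth), and
`mean_ba` is the window-pooled balanced accuracy across the three
leave-one-set-out folds. Small studies like this 10-trial example sit well
below the full-study performance (~0.77–0.78 BA for 80 training trials
with 32 channels) because the SVM and xDAWN filters see few training
windows. `autoplot(report)` draws the per-fold BAs;
`tidy(model)`/`glance(model)` expose fitted detectors in broom style.

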