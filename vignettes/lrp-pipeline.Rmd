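---
title: "Detecting movement intention from the lateralized readiness potential"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting movement intention from the lateralized readiness potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lrpdetect)
```

## The detection problem

Self-paced arm movements are preceded by a slow negative EEG potential —
the lateralized readiness potential (LRP) — that builds up over the motor
cortex contralateral to the moved limb during the last second before the
physical movement onset. An asynchronous brain-computer interface can
exploit this: slide a 1 s window over the ongoing EEG every 50 ms, map
each window to a probability that movement is being prepared, and trigger
assistance when that probability crosses 0.5.

`lrpdetect` implements such a detector together with the full experimental
scaffolding needed to exercise it: a seeded generator of study-shaped
synthetic data, kinematic ground-truth labeling of movement onsets,
reduced channel montages, the sliding-window feature pipeline, an
L1-regularized linear SVM with Platt calibration, and an evaluation
protocol that scores emulated online operation with balanced accuracy
under change-point relabeling. The headline use case is *cross-task
transfer*: train on EEG from bilateral (mirrored) movements, whose onsets
can be labeled from the unaffected arm, and test on unilateral movements
of the other arm — condition C, compared against the no-transfer baselines
A (unilateral→unilateral) and B (bilateral→bilateral).

## The synthetic study generator

`study_config()` fixes the study conditions; `generate_subject_task()` /
`generate_dataset()` realize them. The defaults emulate a self-paced
reaching study: 8 subjects, two tasks, 3 measurement sets of 40 trials
each, 64-channel EEG at 500 Hz referenced to FCz (not a data channel),
and 500 Hz 3-D hand-marker trajectories.

**Trial structure.** Each trial is a resting period drawn uniformly from
[5, 7] s followed by a reach of 0.6 s and a 0.9 s return. A configurable
fraction (default 2%) of trials draws its rest from [4, 4.9] s and is
flagged invalid, exercising the exclusion rule that a valid trial needs at
least 5 s of rest (the sliding grid needs 5 s of pre-onset history).

**EEG.** Background noise is Gaussian with a 1/f power spectrum (spectral
exponent 1, flattened below 0.5 Hz so the variance is finite, DC-free),
pairwise inter-channel correlation 0.2 through a shared component, and SD
10 µV per channel; white noise is available via `noise_model = "white"`.
The readiness potential is injected as a spatial pattern times a temporal
ramp: zero until 1 s before the onset, reaching −6 µV at the onset
(linear by default, half-cosine via `lrp_shape`), returning to baseline
within 0.3 s after it. The spatial pattern is a Gaussian on a schematic
electrode plane (SD 1.2 electrode steps) centred at C1 for unilateral
right-arm movements and symmetrized over C1/C2 for bilateral movements,
normalized to peak weight 1. These amplitudes are free parameters of the
generator: absolute classification accuracies on synthetic data therefore
characterize the chosen amplitude-to-noise ratio, not any real recording.

**Motion.** The hand marker rests at the switch with 0.2 mm SD Gaussian
jitter, then follows a minimum-jerk path of ≈390 mm (30 cm forward, 25 cm
up) over 0.6 s. A fast lift-off transient (25 mm rise within 50 ms,
reabsorbed within 300 ms) is superimposed at the movement onset: the hand
must physically leave the spring-loaded switch for it to release 30 ms
after the onset (the configurable mechanical delay), and a pure
minimum-jerk reach of realistic duration has moved well under 0.1 mm by
then. The transient also gives the onset estimator a sharp kinematic edge
to find, which is what real lift-offs look like to a motion-capture
system.

**What the generator does not emulate.** No eye blinks or EOG/EMG
artifacts (hence no ICA stage — an optional peak-to-peak rejection stands
in for artifact handling), no volume-conduction head model (the spatial
pattern is schematic), no inter-subject variability in amplitude or
latency, no electrode drift. Passing tests on this data show the pipeline
is correct and self-consistent, not that it reaches any particular
accuracy on real EEG.

**Determinism.** Every random draw derives from `seed` through fixed
per-(subject, task, set, component) substreams, so any block can be
regenerated in isolation and identical configurations produce identical
datasets bit for bit.

## Kinematic onset estimation

`kinematic_profile()` re-zeroes the trajectory by its mean over the first
second of the trial, takes the Euclidean distance to that rest position,
differentiates it (first sample 0), low-pass filters the velocity at 4 Hz
(4th-order Butterworth), normalizes by the trial maximum, and multiplies
distance by normalized velocity. The product suppresses both jitter-driven
velocity spikes at rest (distance ≈ 0) and slow drifts of the resting
position (velocity ≈ 0). `estimate_onset()` scans backward from the
hand-switch release for the latest sample whose product magnitude falls
below 0.6 mm — the spatial resolution of a calibrated tracking system.

Numerical choices: the velocity filter is applied zero-phase
(forward-backward) so the filter delay does not bias the onset; a causal
single pass is available via `zero_phase = FALSE`. The backward search is
sample-wise on the 500 Hz grid (2 ms resolution). Trials where no sample
falls below threshold are excluded rather than assigned the trial start,
mirroring the invalid-trial philosophy. On synthetic trials the estimate
lands ~13 ms after the true onset (the product crosses 0.6 mm a few
samples into the lift-off), well inside one 50 ms grid step; the
acceptance script recomputes the recovery rate within ±20 ms. For
bilateral trials `annotate_dataset()` uses the left-hand trace — the arm
whose abilities label the data in the transfer scenario.

## Montages

`get_montage()` serves two families from an editable YAML configuration:
custom left-hemisphere selections of 32/21/16/8/4 channels, nested
concentrically around C1 (the focus of right-arm movement planning), and
standard extended 10-20 constellations of 32/21/16 channels (16 is the
smallest standard constellation). The shipped memberships are a
motor-centred approximation — the tests assert the structural invariants
(nesting, C1 membership, no right-hemisphere labels, sizes) rather than
exact identities, and a user file can override any set.

## Feature pipeline

Per trial, 81 windows of 1 s are cut every 0.05 s spanning [−5, 0] s
relative to the onset, half-open on the sampling grid. Each window is
processed independently:

1. **Standardization** per channel with the window's own mean and SD
   (zero-variance channels map to zeros, not NaN). Using window-local
   statistics matches the window-wise processing model of an online
   system; no continuous-signal standardization is implemented.
2. **Decimation** 500 → 20 Hz by DFT-domain spectral resampling: the
   window's spectrum is truncated at the 10 Hz target Nyquist and
   re-evaluated on the 20-sample grid. On a finite window this is the
   exact brick-wall anti-alias decimator. An IIR anti-alias filter
   (Chebyshev/Butterworth + subsampling) was rejected because its
   forward-backward transients on a 1 s window leak broadband energy into
   the low-frequency band right at the window edge — where the features
   live — and measured stop-band attenuation fell below 20 dB near the
   band edge. With spectral resampling, stop-band tones at resolvable
   (integer-Hz) frequencies are annihilated to machine precision. Tones
   at half-bin frequencies leak through any 1 s-window DFT method — an
   inherent resolution limit shared by the FFT band-pass itself.
3. **FFT band-pass** 0.1–4 Hz on the 20-sample window: bins whose centre
   frequency lies in [0.1, 4] Hz are kept — bins 1–4 Hz, DC removed;
   edge-bin inclusion is inclusive.
4. **xDAWN spatial filtering** to 4 pseudo-channels. The filters are fit
   with the two-class epoch formulation: maximize the energy of the
   LRP-class average (evoked) response against the pooled energy of all
   training windows, i.e. the generalized symmetric eigenproblem
   `Σ_evoked v = λ Σ_pooled v`, solved by Cholesky whitening plus a
   symmetric eigendecomposition; the top 4 eigenvectors, eigenvalue-
   descending, are the filters. Signs are fixed (largest coefficient
   positive) for determinism. Rank-deficient pooled covariances get a
   ridge of `1e-8 · trace/dim`. The implementation is verified against a
   dense generalized eigensolver on toy problems.
5. **Features**: the last 4 samples of each pseudo-channel — the final
   0.2 s at 20 Hz — flattened channel-major (pseudo-channel 1's four
   samples first): 16 features per window, then z-scored with the
   training set's per-feature mean and SD (zero-SD features use SD 1 and
   are flagged).

All fitted artifacts — xDAWN filters, feature normalizer, SVM, Platt
calibration — come from training folds only; models carry a `fold_id`
tag for bookkeeping.

## Classifier

Per valid training trial, exactly five windows become instances: [−1.10,
−0.10] and [−1.00, 0.00] s as LRP, and [−3.05, −2.05], [−3.25, −2.25],
[−3.50, −2.50] s as NoLRP (2:3 per trial). The SVM minimizes

`||w||₁ + C Σᵢ sᵢ max(0, 1 − yᵢ(xᵢᵀw + b))²`

with class weights `s` of 1 (NoLRP) and 2 (LRP) and an unpenalized
intercept, solved in the primal by FISTA proximal gradient with
soft-thresholding (deterministic; convergence at relative step 1e-10 or
5000 iterations; the Lipschitz constant comes from the exact largest
eigenvalue of the weighted Gram matrix, cheap at 16 features). The L1
penalty zeroes redundant features. `C` is selected by stratified 5-fold
cross-validation over the seven log-equispaced values `10^-6 … 10^0` —
the only natural reading of seven equal-spaced values spanning six
decades — scored by balanced accuracy (consistent with the evaluation
metric), ties resolved toward the smaller, sparser `C`. The final SVM is
refit on the whole training set and Platt's sigmoid `p = plogis(A·score +
B)` is fitted on its training decision values with the classic smoothed
targets (a 3-fold held-out calibration is available via
`calibration = "cv"`). A window is declared LRP iff `p` strictly exceeds
0.5.

## Evaluation protocol

`make_splits()` enumerates the three leave-one-set-out folds. For each
fold, the detector predicts all 81 windows of every held-out trial, and
per-window ground truth is derived from the prediction sequence itself by
change-point relabeling: windows before the one starting at −2.00 s are
fixed NoLRP and the [−1.00, 0.00] s window is fixed LRP; inside the range
between those boundaries the label change point is located by scanning
the predicted labels backward in time from the [−1, 0] window — the first
run of three consecutive NoLRP predictions places the change point
immediately later than the run; everything before it becomes NoLRP truth,
everything past it LRP truth; with no such run the whole range is LRP (a
long planning phase). Fixed boundary labels are applied last, so the
truth is always a single monotone NoLRP→LRP step. Boundary-window
*predictions* do participate in the scan; only their truth labels are
fixed. If every in-range prediction is NoLRP, the first backward run is
the latest triple and only the fixed [−1, 0] window remains LRP — the
scan convention, applied literally. The implementation is checked against
an independently coded brute-force scan on all 2²¹ in-range patterns.

Balanced accuracy pools windows over all test trials of a fold (per-trial
averaging is a plausible alternative; pooling weighs every window
equally). Because the truth is derived from the predictions, a detector's
own predictions are not exchangeable with chance — the protocol's
unbiasedness is instead verified by the shuffle control: predictions made
independent of the derived truth (by permuting a sequence's labels) have
expected TPR = q and TNR = 1 − q for any truth, hence BA exactly 0.5.

Condition C trains on two bilateral sets and tests on the held-out
unilateral set of the same split index; train and test are always
disjoint, and in condition C additionally from different tasks.

## Problem sizes and observed behaviour

The test suite runs miniatures (1–2 subjects, 4–10 trials per set, 8–16
channels) for unit and property checks, plus the full default study
(8 subjects × 3 × 40 trials, 64 channels) for the end-to-end
cardinalities and the transfer comparison; the acceptance script repeats
the full-study computations from scratch. At the default
amplitude-to-noise ratio (−6 µV peak against 10 µV 1/f noise) the
full-study runs land near 0.78 mean BA for condition A and within ~0.01
of it for condition C — the transfer penalty is small, which is the
substantive claim the pipeline supports. The absolute level is set by the
generator's free amplitude parameter: after window-wise standardization
and the DC-removing band-pass, the informative part of the ramp is ~2 µV
against ~5 µV of in-band noise per channel, and the resulting per-window
separability caps BA in the high 0.7s. We deliberately did not raise the
synthetic amplitude to advertise a rounder number.

## ERP analysis

`epoch_baseline()` band-pass filters the continuous recording 0.1–4 Hz
and cuts [−1.5, 0] s epochs, baseline-corrected on [−1.5, −1] s;
`grand_average()` pools epochs (incrementally across subjects) with the
count reported. The continuous filter is a zero-phase cascade of
4th-order Butterworth high-pass (0.1 Hz) and low-pass (4 Hz) stages — a
direct band-pass design of that order is numerically unstable at a
0.1 Hz edge on a 500 Hz grid (measured gain explosions), while the
cascade realizes the same band stably; channels are demeaned first to
shrink the high-pass edge transient. This continuous-signal filter is
intentionally different from the per-window FFT filter of the detection
pipeline: ERP visualization wants smooth, transient-free traces.

## Known limitations

* Absolute balanced accuracies on synthetic data reflect the configured
  amplitude-to-noise ratio only; no claim transfers to real recordings.
* The montage memberships are a schematic approximation of a
  motor-centred selection; real electrode choices should be supplied via
  the YAML override.
* The change-point relabeling derives truth from predictions; it measures
  self-consistent online behaviour, not latency-true detection accuracy.
* The generator's noise has no oscillatory (alpha/beta) structure, no
  artifacts, and a rank-1 inter-channel correlation — all favourable to
  spatial filtering compared with real EEG.
* Dataset export writes plain TSV matrices plus a JSON manifest; no
  binary EEG container formats are produced.
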