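---
title: "Decoding gait speed changes from single-trial EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding gait speed changes from single-trial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During treadmill walking, a subject alternates between standing (0 km/h)
and walking at 1 or 2 km/h, following the block order 0-1-2-1-2-1 repeated
three times and ending in rest: 19 blocks of 20 s, 380 s per session, ten
sessions per subject. In 7 of the 10 sessions visual cues pace the speed
changes (*cued*); in the remaining 3 the subject self-initiates them
(*uncued*). A linear encoder detects the moment the subject's speed
deviates from the belt by more than 0.12 m/s; the belt then adapts with a
4 s acceleration or 8 s deceleration ramp. Each detection is a
*speed-change onset*. The scientific question is whether a single-trial
EEG classifier can distinguish 8 s epochs around these onsets
(*change-speed*, -4 s to 4 s) from epochs of steady walking
(*constant-speed*, -12 s to -4 s), and whether the information it uses is
cortical (mu and beta event-related desynchronization, ERD, over
posterior parietal cortex) rather than ocular, muscular or mechanical.

This package re-implements the complete analysis as a tested pipeline
and pairs it with a synthetic-EEG generator so that every stage can be
verified end to end without access to the original recordings, which
were never deposited.

## Pipeline overview

Per subject, a leave-one-session-out cross-validation (10 folds):

1. **Preprocessing.** 64 channels are band-passed 1-45 Hz with a
   Hamming-window FIR whose order follows the automatic heuristic (below),
   then resampled to 256 Hz.
2. **Spatial filters.** Two-pass ICA on the concatenated training
   sessions: segments of 0.5 s whose joint log-probability deviates more
   than 5 SD from the mean are dropped; ICA is run; a second segment
   rejection uses the probability of the component activations; the
   surviving signal is band-passed 8-40 Hz (425 taps at 256 Hz) and ICA
   runs again. The final unmixing matrix defines the fold's components.
3. **Component rejection.** Each scalp map is explained by a single
   equivalent current dipole in a 4-shell spherical head model.
   Components are rejected when the fit leaves more than 10% residual
   variance, the dipole sits beyond 70% of the sphere radius, or below
   z = 0 (all strict inequalities); a two-criterion detector flags eye
   components (frontally dominated map together with <4 Hz dominance or
   high temporal kurtosis).
4. **Features.** Per epoch and retained component, a complex Morlet
   decomposition on 20 log-spaced frequencies (8-40 Hz) and 50 windows of
   107 samples covering -3789 to +3789 ms; squared magnitude in dB.
5. **Component selection.** One L1 logistic model over all candidate
   components' features; nonzero weights are counted per component and
   the scree-test acceleration factor on the sorted counts sets the
   cut: components ranked strictly before the elbow are kept (min. one).
6. **Epoch QC.** An epoch is discarded when any retained component's
   mean 20-40 Hz perturbation versus the training constant-speed baseline
   leaves +25/-100 dB in any window.
7. **Classifier.** PCA to 90% cumulative variance (training statistics
   only), then L1-regularised logistic regression with an internal
   5-fold cross-validation choosing the penalty; change-speed is called
   when P > 0.5.
8. **Evaluation.** Fold confusion matrices are summed; class-wise
   normalised accuracy, Cohen's kappa and the corrected adjusted-Wald
   lower bound `k_l = k_hat - z * sqrt(p_hat(1-p_hat)/((N+4)(1-p0)^2))`
   with `p_hat = (C+2)/(N+4)`; kappa is significant when `k_l > 0`.
   Cued and uncued test folds are also pooled separately, each
   change-speed subclass (0->1, 1->2, 2->1, 1->0) is scored against the
   constant trials at its preceding speed, and a pre-onset variant
   retrains the classifier on windows wholly before the onset.

The pseudo-online path reuses each fold's spatial model and retained
component set: training uses
four jittered 2 s windows per trial and class, testing slides nine 2 s
windows per trial; a trial's all-or-nothing score is the maximum of the
moving average (order m = 1, 2, 3) of its nine probabilities, giving an
ROC/AUC per m, and the per-bin output quartiles give the decoder
time-course.

## The FIR order heuristic

Each passband edge proposes a transition bandwidth
`min(max(0.25 * edge, 2 Hz), distance of the edge to the nearer of 0 or
Nyquist)`; the design uses the minimum over both edges. The length is
`ceil(3.3 * fs / tb)` rounded up to the next even order, plus one tap, and
the -6 dB cutoffs sit half a transition bandwidth outside the passband.
This reproduces both published designs exactly: 1-45 Hz at 2048 Hz gives
6761 taps with cutoffs 0.5/45.5 Hz, and 8-40 Hz at 256 Hz gives 425 taps
with cutoffs 7/41 Hz. We interpret the published "order" values as tap
counts (estimated even order + 1); no other reading reproduces both
numbers.

## The synthetic generator

`simulate_session()` renders the session plan into belt and
subject-minus-belt speed traces, detects onsets at +/-0.12 m/s, and sums
forward-projected dipolar sources plus white sensor noise:

* **Cortical ERD sources.** A parietal mu source at (-12, -40, 40) mm
  (8-15 Hz, -3 dB during 0-2 s after every onset), a parietal beta source
  at the same location (16-31 Hz, -1.5 dB), and a weaker motor mu source
  at (15, -35, 38) mm (-1 dB) present in a configurable subset of
  subjects. Carriers are band-limited noise under a slow lognormal
  amplitude envelope (the waxing/waning of real rhythms; the resulting
  supergaussianity is also what makes the sources identifiable by ICA);
  the ERD multiplies them by a raised-cosine-edged envelope dropping
  the configured dB. The
  source depths (54-58 mm radius) are chosen where retained equivalent
  current dipoles must lie: inside 70% of the sphere radius, or the
  pipeline's own dipole rejection would discard the very components that
  carry the effect.
* **Background.** Six 1/f sources at fixed per-subject random locations.
* **Artifacts.** A blink source near the eyes (stereotyped 350 ms pulses
  at 0.2 Hz), two EMG sources at the neck (20-100 Hz noise, tonic level
  plus 0.5 s bursts, gated by walking), and a step-locked impulse source
  (5 harmonics of the stepping rate, 0.75 Hz at 1 km/h and 0.95 Hz at
  2 km/h, active only while the belt moves).

Uncued sessions draw steady-walk durations from Gaussians with mean
17.4 s / SD 5.35 after accelerations and 12.8 s / SD 6.51 after
decelerations (floored at 6 s, truncated at 380 s). A consequence worth
knowing: with these statistics roughly a third of uncued onsets lack the
12 s of preceding steady walking the constant-speed epoch needs, so
uncued sessions contribute fewer trials than cued ones - the pipeline
drops such trial pairs and logs them.

Every source draws its waveform from a seed derived from (session seed,
source index), so a source realisation does not depend on which other
sources are enabled; this is what makes the per-channel
variance-decomposition check meaningful. Sensor noise defaults to 1 uV
SD at the acquisition rate, a value chosen once so that the default
cohort's cross-validated accuracy falls in the 70-85% range typical of
single-trial EEG decoding; it lives in the configuration, not in code.

What the generator does **not** emulate: biomechanically realistic gait,
volume-conduction errors (the forward model used for simulation and for
dipole fitting is the same 4-shell sphere, so fits are optimistic),
electrode drift or impedance changes, non-stationary background rhythms,
and visual-cue-evoked activity. Passing the end-to-end checks therefore
shows the pipeline recovers what it assumes, not that the assumptions
hold for real recordings.

## The forward model and dipole fitting

The 4-shell concentric sphere (radii 71/72/79/85 mm; conductivities
0.33/1.0/0.0042/0.33 S/m - standard BESA-style defaults) is solved per
Legendre degree by a small linear system for the interface coefficients;
60 degrees are summed (the last term's relative contribution is checked,
and the public forward operator raises a convergence error when it
exceeds 1e-4, which cannot happen for legal cortical sources). With all
conductivities equal the solver agrees with the closed-form
homogeneous-sphere solution to better than 1e-6 relative error; the
closed form used as the test oracle was derived independently by summing
the series with generating-function identities.

The dipole fitter searches location with Nelder-Mead from 8 seeded
restarts on the 60%-radius sphere (tolerance 1e-8 on the residual
variance), solving the moment linearly at every location. Following
standard practice in BESA-style fitters, the search may leave the brain
shell: the series is evaluated as a formal extension up to just below
the scalp radius. This matters twice - the 70%-radius rejection
heuristic (59.5 mm) and the far-field QC pool (radial fraction > 0.90,
i.e. beyond the 71 mm brain shell) are only meaningful if fits can land
there. The public forward operator, by contrast, enforces the
inside-the-brain-shell domain.

## Numerical and design choices

* **TF window grid.** Window centres are spaced evenly in seconds from
  54/fs after the epoch start to 54/fs before its end. For the 8 s epoch
  this reproduces the published -3789 to +3789 ms grid; for the 2 s
  sliding epoch, -0.79 to +0.79 s. Cycle counts interpolate linearly from
  3 to 7.5 across the 20 bins (a literal increment of 0.5 per bin cannot
  span 20 bins between those endpoints). Wavelets are L2-normalised;
  only power ratios matter downstream. Power is floored at 1e-20 before
  the dB transform.
* **Fused decimation.** The pipeline applies the 1-45 Hz band-pass and
  the 8x decimation in one FFT pass (the filtered spectrum is truncated
  to the decimated band before the inverse transform). This equals
  filter-then-decimate up to the aliased stopband residue (~1e-4
  relative, verified in the tests) and roughly halves preprocessing
  time. The standalone `apply_zero_phase()`/`resample_recording()`
  operators implement the literal two-step path.
* **ICA.** FastICA with symmetric orthogonalisation and tanh contrast
  on whitened data (any algorithm recovering seeded synthetic mixtures
  with Amari index < 0.1 is acceptable for this stage). Dimensionality
  is capped at 20 principal components (and at the numerical rank),
  recorded in the model provenance; the cap bounds fold cost and
  comfortably covers the ~13 synthetic sources. The ICA fit uses an
  evenly strided subsample of at most 18,000 cleaned samples (the
  second pass filters evenly spaced contiguous chunks); the unmixing is
  applied to all data. The pipeline uses 3 dipole-fit restarts per
  component (the standalone fitter defaults to 8) - with a shared exact
  forward model the fits converge from essentially any start.
* **Probability score.** Histogram densities with 50 bins per channel;
  "exceeds the average distribution by 5 SD" is read as a two-sided
  5-SD rule on the segment score. The second rejection pass scores
  component activations.
* **Scree elbow.** Components ranked strictly before the
  maximum-acceleration rank are retained (minimum one); with fewer than
  three candidates or all-equal counts, all are retained. Ties in the
  count sort break by ascending component index.
* **Kappa chance term.** `p0` is computed from the confusion-matrix
  marginals (Cohen's convention); for the balanced designs here it is
  approximately 0.5. Significance uses the two-sided 95% quantile.
* **Pre-onset variant.** Windows whose centres lie more than half a
  window before the onset (24 of the 50), with PCA and classifier
  retrained per fold on the same spatial models.
* **Epoch conventions.** Epoch windows are half-open `[start, end)` in
  samples and the onset sample belongs to the change epoch. Event sample
  indices use the time convention `round(onset_s * fs)`; resampling
  rescales them rounding half away from zero. Trials lacking 12 s of
  preceding constant speed are dropped (paired, so classes stay
  balanced).
* **Cluster metric.** Dipole coordinates and scalp-map principal
  components (90% variance) are z-scored blockwise with equal weight;
  scalp maps are sign-aligned (largest-magnitude channel positive)
  because ICA signs are arbitrary. Outliers are members more than 5 SD
  (within-cluster distance z-score) from their centroid; centroids are
  refit once after removal.
* **Montage.** An idealized spherical 10-10 construction: midline and
  outer-ring electrodes at 18-degree steps, interior rows by great-circle
  interpolation. It is exactly left-right symmetric; it is not a
  digitised cap.

## Problem sizes

The package's own verification uses a 2-subject synthetic cohort at the
full session design (10 sessions x 380 s, 64 channels simulated at
2048 Hz and analysed at 256 Hz) for the end-to-end checks, with
per-operation tests on smaller constructed inputs (e.g. 8-source
mixtures of 30,000 samples for ICA recovery, 50 random interior dipoles
for the inverse check, 2000 replicates for the kappa coverage check).
The analysis scripts under `analysis/` run the same cohort.

## Known limitations

* The generator and the fitter share the same head model; localisation
  accuracy on real EEG (skull conductivity errors, electrode placement)
  will be worse than the tests suggest.
* The eye detector is a two-criterion simplification of full
  artifact-template methods; its thresholds were calibrated on this
  generator's blink morphology.
* Only integer-factor resampling is implemented (the study needs 8:1).
* Repeated-measures ANOVA with sphericity corrections and anatomical
  (Talairach/Brodmann) labelling of cluster centroids are out of scope;
  only the paired t-tests are provided.
* True online (causal) filtering is not implemented; the pseudo-online
  path is an offline emulation with causal window placement.
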