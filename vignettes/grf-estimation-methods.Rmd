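---
title: "Estimating three-axis ground reaction force from plantar load cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating three-axis ground reaction force from plantar load cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grfnet)
```

## The problem

Ground reaction force (GRF) — the 3-axis force the ground exerts on the
foot — is the basic external load in gait analysis and inverse dynamics.
The gold-standard instrument, a laboratory force plate, measures one step
per plate, which makes multi-step and out-of-lab studies impractical.
A wearable alternative instruments a shoe with three rigid uniaxial load
cells under the mid-heel, the 1st metatarsal head and the 5th metatarsal
head. Load cells avoid the drift and deformation artifacts of flexible
force-sensitive resistors, but three uniaxial channels do not determine the
3-axis GRF algebraically: the mapping from regional plantar load to
vertical, anterior–posterior (AP) and medial–lateral (ML) force must be
learned.

`grfnet` implements that mapping end to end: signal preprocessing and
instrument synchronization, a sequence-to-sequence LSTM regressor, a
validation suite, and a synthetic gait generator that stands in for human
walking data, which are not redistributable.

## Preprocessing

The two instruments record at different native rates (load cells nominally
100 Hz, force plate 120 Hz). Each trial is processed as:

1. **Resampling to 200 Hz** by linear interpolation onto the uniform
   destination grid. Because all content of interest is subsequently
   limited to 15 Hz — far below either Nyquist frequency — interpolation
   error is negligible, and the operation is simple and exactly
   reproducible. (A dedicated bandlimited resampler would matter only if
   the filter cutoff approached the source Nyquist rate.)
2. **Lowpass filtering** with a 4th-order Butterworth at 15 Hz. Filtering
   is zero-phase by default: the filter runs forward and backward, so the
   effective amplitude response is the squared single-pass response (0.5 at
   the cutoff) and there is no group delay. The zero-phase choice matters
   because downstream statistics are event *timings*; a causal 4th-order
   filter at 15 Hz would add roughly 15–20 ms of lag and bias the
   heel-strike and mid-stance estimates. A causal mode is retained as an
   option for streaming-style use. Before filtering, the series is padded
   by odd reflection (about three cutoff periods) and the filter is started
   from steady-state initial conditions, so edge transients decay inside
   the pad; both channels of both instruments are filtered identically.
3. **Heel-strike detection**, independently per instrument: the first
   sample exceeding 10 N that stays above threshold for at least 25 ms
   (force-plate vertical channel; load-cell heel channel). The debounce
   prevents swing-phase noise from triggering a false contact.
4. **Synchronization and cropping**: both series are shifted so their
   detected heel strikes coincide at index 1, then cropped to the
   force-plate stance interval (onset to the last sample of the contiguous
   supra-threshold region). The load-cell sum is appended as a fourth input
   channel, computed exactly as the elementwise sum of the three filtered,
   cropped channels.

Indices are 1-based and stance intervals inclusive, following R
convention.

## The estimator

The estimator is a sequence-to-sequence LSTM mapping the four input
channels (heel, met1, met5, sum; newtons) to the three GRF axes at every
200 Hz time step. The architecture is three LSTM layers of 200, 50 and 200
units, each followed by a fully connected (linear) layer of the same
width, and a final 3-unit linear regression head. The width of the
interleaved fully connected layers is a design choice: we read "each layer
connected to a fully connected layer" minimally, as a learned linear
projection matching its LSTM's width.

Training follows the recipe the architecture was designed with: Adam,
learning rate 0.01, minibatch size 32, 1000 epochs by default (package
experiments use a reduced-epoch mode, see below). Additional choices the
recipe leaves open:

* **Normalization.** Inputs and targets are z-scored per channel with
  statistics from the training split only, stored with the model and
  inverted at prediction time. Without this, the vertical channel
  (~700 N) dominates the MSE and the AP (~100 N) and ML (~30 N) axes are
  effectively ignored.
* **Variable-length batching.** Stance duration varies by subject, so
  sequences in a minibatch are padded with zeros to the batch maximum and
  the loss is averaged over unpadded positions only. Because the
  recurrence runs forward in time and padding is at the tail, predictions
  at valid positions are unaffected by padding.
* **Gradient clipping.** At learning rate 0.01 an unclipped LSTM
  occasionally diverges; gradients are clipped to a global norm of 1.
* **Checkpoint selection.** No early stopping; instead the checkpoint with
  the lowest validation loss is returned (`selection = "best_validation"`),
  which matches a fixed-epoch recipe while guarding against late
  overfitting.
* **Determinism.** Initialization and batch shuffling use a dedicated
  Mersenne-Twister stream seeded from the model configuration, so a fit is
  bit-reproducible for a fixed seed and single-threaded BLAS.

The implementation (forward pass, backpropagation through time, Adam) is
written in RcppArmadillo; the analytic gradients are verified against
finite differences in the test suite.

Validation is strictly **subject-wise**: train, validation and test sets
contain disjoint subjects (the fitter refuses overlapping subject ids), so
reported accuracy reflects generalization to unseen people, not unseen
strides of seen people.

## The synthetic gait generator

The human dataset behind this design (81 subjects, two instrumented-shoe
walking trials each) is not redistributable, so the package ships a
generator that emulates its structure with known ground truth. Per
subject it draws body weight (normal, mean 650 N, sd 90 N, truncated to
400–1000 N), stance duration (normal, mean 0.59 s, sd 0.04 s, truncated to
0.4–0.9 s), per-channel gains (±20% uniform jitter), and a metatarsal
timing group: with probability `fraction_similar_timing` (default 0.25)
the 1st and 5th metatarsal load essentially simultaneously ("similar", as
observed in a minority of real subjects); otherwise the 5th metatarsal
loads first ("different", the common pattern).

Stance-phase waveforms are analytic functions of the stance phase
`p = (t - heel_strike) / stance_duration`:

* vertical: two Gaussian bumps (amplitudes 1.2 and 1.15 body weights at
  phases 0.25 and 0.75, width 0.18) under a `sin(pi * p)^0.5` endpoint
  taper — the classic M-shape;
* AP: a negative (braking) then positive (propulsive) half-sine lobe pair
  crossing zero at the subject's mid-stance phase `p0`, amplitude 0.18 BW;
* ML: a small single lobe whose amplitude couples to the subject's
  metatarsal gain ratio;
* load cells: Gaussian bumps at the heel (phase 0.22), 5th metatarsal
  (0.60) and 1st metatarsal (0.72) centers, width 0.15.

Two couplings make the estimation problem well-posed rather than
trivially constant: the AP crossing phase is
`0.45 + 0.25 * (met1_center - met5_center) + N(0, 0.01)`, and the ML
amplitude is `(0.03 + 0.02 * gain_met1 / gain_met5) * BW` — both functions
of quantities that also shape the observable load-cell channels, so a
consistent estimator can in principle recover them.

The load-cell bump width (0.15) is the generator's calibration parameter:
it is set so that the pooled correlation between the load-cell sum and the
vertical GRF over default datasets falls near 0.84, the value reported for
real instrumented shoes, and the acceptance suite checks the generator
stays inside [0.80, 0.90]. Swing phase carries zero-mean noise of 1.5 N sd
on the load cells ("very small values" while the sensor rides the foot)
and exact zeros on the force plate; in-stance sensor noise is 2 N sd on
both instruments. Each trial is padded with 0.4 s of swing on both sides,
enough for the zero-phase filter transients to decay so synchronization is
provably lag-invariant.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: inter-stride waveform variability within
a subject beyond sensor noise, foot-angle-dependent load transfer, sensor
placement error, in-toeing and other atypical patterns, soft-tissue and
shoe-compliance dynamics, and any pathological gait. Accuracy figures on
synthetic data validate the *pipeline* (preprocessing, training,
evaluation machinery), not clinical performance.

## Numerical choices and degenerate inputs

* Onset detection raises a typed "no onset" error when nothing crosses
  threshold; synchronization names the failing instrument.
* The mid-stance crossing is the first negative-to-positive AP sign change
  at or after the AP global minimum (skipping spurious near-zero flips at
  contact), with linear sub-sample interpolation; an all-positive or
  all-negative series raises a typed "no crossing" error, and evaluation
  excludes such trials with a logged count.
* The "equal" timing class means |error| below half a sample period
  (2.5 ms at 200 Hz).
* Bland–Altman uses differences `estimated - measured`, the sample sd
  (n−1), limits of agreement at ±1.96 sd, a t(n−1) confidence interval for
  the bias, and the classical `sd * sqrt(3/n)` standard-error
  approximation for the limits.
* Correlation and RMSE pool concatenated samples across test segments per
  axis; per-trial averaging is deliberately not the default since the
  reference results report one value per axis.

## Experiment scale

The package's end-to-end experiment (acceptance suite and
`scripts/acceptance.R`) uses 60 synthetic subjects × 2 trials split
subject-wise 37/12/11, with training reduced to 200 epochs,
`fraction_similar_timing = 0.5` so both timing subgroups are populated in
the 11 test subjects, and a learning rate of 0.001. The learning rate is
the one place the desk-scale experiment departs from the default recipe:
with Adam, every optimizer step perturbs each parameter by roughly the
learning rate, so lr 0.01 imposes a convergence floor (normalized
validation MSE ≈ 0.12 on this task, vertical r ≈ 0.88) that clean
synthetic waveforms expose but that noisier real signals would mask. At
lr 0.001 the identical experiment converges to a validation MSE of ≈ 0.05
within 100 epochs (vertical r ≈ 0.97). The 1000-epoch / lr 0.01 recipe
remains the package default. Unit tests use much smaller widths and
subject counts; the statistics oracles run at n up to 1000.

## Known limitations

* The estimator is trained and validated on level-ground walking at
  self-selected speed; nothing here supports running, turning, or stairs.
* Center-of-pressure / point-of-application estimation is out of scope.
* The LSTM runs on CPU; a 1000-epoch fit at full scale is a long
  computation (hours, not minutes).
* The generator's waveform families are smooth analytic shapes; models
  that exploit their smoothness may look slightly better on synthetic
  data than they would on real signals.
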