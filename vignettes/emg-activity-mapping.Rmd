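---
title: "Mapping forearm muscle activity from grid sEMG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping forearm muscle activity from grid sEMG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emgmap)
```

## The problem

High-density surface EMG (sEMG) records muscle activity with a grid of
electrodes — here 14 columns wrapped around the forearm circumference
(ulnar–radial direction, coordinate `x`) by 8 rows along the limb
(proximal–distal, `y`), with 15 mm inter-electrode distance (IED). During
cyclic wrist or single-finger movements, different forearm muscles produce
spatially distinct patches of activity on this grid. `emgmap` implements the
full analysis chain that turns raw monopolar grid signals plus synchronized
joint-angle traces into:

1. conditioned envelopes per electrode,
2. movement cycles segmented from the kinematics,
3. motor modules (non-negative matrix factorization of cycle-averaged
   envelopes) with a data-driven module count,
4. segmented activity clusters with centre-of-gravity (COG), overlap and
   displacement statistics, and
5. joint-angle reconstruction from reduced electrode subsets.

Because no public recordings of this protocol exist, the package ships a
synthetic generator that plants known spatial sources, temporal modules,
condition effects and artifacts. Every downstream claim the package makes is
tested as a *recovery* statement: the pipeline is run end-to-end on
synthetic cohorts and must recover what the generator planted.

## The synthetic generator

A planted source couples an isotropic Gaussian spatial footprint on the grid
(centre in continuous grid units, spread `sigma` in IED units) to a
nonnegative temporal activation profile defined on the normalized movement
cycle (500 phase points). The surface signal of one source is

```
x_ch(t) = w_ch * a(phase(t)) * (1 + amp_jitter * z_cycle) * carrier(t)
```

where `w_ch` is the Gaussian weight at the electrode, `a` the activation
profile and `carrier` a zero-mean broadband noise carrier band-limited to
20–450 Hz, shared across channels of one source — the standard surrogate for
interference-pattern EMG. Channels sum their source contributions plus
band-limited instrumentation noise, 50 Hz interference (with odd harmonics
at 150 and 250 Hz, amplitudes 1/k), and optionally "dead" electrodes
replaced by low-amplitude uncorrelated noise. The rectified-and-smoothed
envelope of such a signal is proportional to `w_ch * a(phase)`, so the
planted structure lives on exactly the axes the pipeline reconstructs.

Key defaults and why:

* **fs = 2048 samples/s, 2 s holds, trapezoidal cycles, 20 cycles for wrist
  tasks / 12 for finger tasks** — the acquisition protocol the pipeline is
  designed for. The joint angle is generated at 50 samples/s like a
  sensorized-glove stream and resampled in the pipeline.
* **SNR 15 dB, 10 % amplitude jitter, 5 % cycle-duration jitter** — the
  protocol source gives no noise statistics for its recordings; these values
  are a realistic mid-range choice for surface recordings with good skin
  preparation, set once so that the repeatability (CMC) analyses operate in
  a meaningful regime, and not revisited.
* **Three default wrist sources** — an "extensor" source active in the
  second half of the cycle, a "flexor" source in the first half, and a
  weaker third source around mid-cycle, with nearly non-overlapping phase
  profiles and distinct footprints. This makes the planted envelope
  structure effectively rank 3 with unequal component energies, so the VAF
  criterion has a well-defined answer (N\* = 3) rather than a knife-edge
  one.
* **Condition effects** enter as a rigid ulnar–radial displacement of all
  source centres (`condition_shift_x`, applied in `x` only, since the
  displacement of interest is circumferential) and per-source amplitude
  gains in the non-reference condition.

What the generator does **not** emulate: physiological motor-unit
recruitment, volume-conductor effects, inter-muscle crosstalk beyond
Gaussian footprint overlap, electrode-skin impedance drift, or movement
artifacts. Passing recovery tests therefore shows the *pipeline* is correct
and well-calibrated, not that real forearm data will be as clean.

## Signal conditioning

* **Band-pass**: 4th-order Butterworth, 20–450 Hz, applied
  forward–backward. Zero-phase filtering is essential because envelope
  timing is compared across streams; it also squares the magnitude
  response, which the filter tests account for. The filters are designed by
  `signal::butter`; the forward–backward pass runs in compiled code over
  whole channel matrices with odd-reflection padding and steady-state
  initial conditions (verified against `signal::filtfilt` to ~1e-10).
* **Power-line removal** by spectral interpolation: around each harmonic
  k·50 Hz (k = 1..5) the magnitude spectrum within ±1 Hz is replaced by the
  linear interpolation of the mean magnitudes of the ±1–3 Hz flanking
  bands; phases are kept, conjugate symmetry is restored, and the record is
  mirror-padded to a fast FFT length. On records of tens of seconds this
  suppresses a planted line by well over 20 dB while leaving the broadband
  spectrum untouched; on very short records suppression is limited by
  spectral leakage — a property of the method itself.
* **Envelope**: rectification followed by a zero-phase 4th-order
  Butterworth low-pass at 1 Hz; rare negative ringing values are clipped to
  0 because the factorization requires nonnegative input.
* **Bad-channel detection** runs on envelopes. The amplitude screen uses
  the robust z-score (median/MAD) of the per-channel log-RMS: channels
  below −3.5 are dead contacts. A channel *above* +3.5 is flagged only when
  its envelope is also spatially incoherent (maximum |correlation| with its
  4-connected neighbours below 0.5); this guard exists because on tasks with
  one compact source most of the grid sits at the noise floor, the MAD
  collapses, and a plain two-sided rule would flag the genuinely active
  electrodes. Channels whose best neighbour correlation falls below 0.2 are
  flagged regardless. More than 50 % flagged raises an error (systemic
  failure). Detection happens once, on envelopes, and the mask is honoured
  by every later stage.

## Cycles, time normalization and CMC

Flexion is mapped to increasing angle. A state machine tracks the running
extremum during each extension hold and declares a flexion onset at the
first sample exceeding that extremum by 2°; cycles span consecutive onsets,
and the partial segments before the first and after the last onset are
discarded. Note the 2° rule fires a deterministic delay after the true
movement start (threshold / ramp slope), bounded additionally by the 50 Hz
kinematic resolution (~41 EMG samples); the tests check onsets against
ground truth plus this known delay.

Cycles whose range of motion falls outside the Tukey fences
(Q1 − 1.5 IQR, Q3 + 1.5 IQR) of the task's ROM distribution are excluded
(the upstream criterion is unspecified beyond "outliers on the basis of the
range of motion"; Tukey fences are the conventional choice). Envelopes and
angle of each kept cycle are linearly interpolated onto 500 phase points.

Repeatability uses the coefficient of multiple correlation in the
within-day form of Kadaba et al. (1989):

$$\mathrm{CMC} = \sqrt{1 - \frac{\sum_{c,t}(y_{ct} - \bar y_t)^2 / (T(C-1))}
{\sum_{c,t}(y_{ct} - \bar y)^2 / (CT-1)}}$$

with C kept cycles and T = 500 phase points. Under this normalization
mutually independent cycles give CMC ≈ 0 and identical cycles give 1; the
ratio is clipped so the root stays real. Which CMC variant the original
analyses used is not documented; the within-day form is the one whose null
behaviour matches a repeatability statistic, and it is the documented choice
here. Summary CMC values are medians over *active* channels — channels whose
envelope peak (95th percentile) exceeds twice their own baseline (10th
percentile), evaluated away from the record edges to avoid filter
transients.

## Motor modules (NNMF)

Cycle-averaged envelopes of all tasks are concatenated per subject into a
channels × (tasks·500) matrix M and factorized as M ≈ A·S with temporal
modules S (N × time) and spatial coefficients A (channels × N), both
nonnegative, by Lee–Seung multiplicative updates minimizing
‖M − A·S‖²_F. To escape local minima the fit restarts from (by default) 100
random initializations — tests and cohort analyses use 20 — and keeps the
lowest-SSE solution; each restart seed derives from one master seed, so
results are reproducible. The scale indeterminacy is fixed by unit-maximum
temporal modules with the inverse scale pushed into A, which is what makes
map weights comparable across conditions.

Reconstruction quality is VAF = 1 − SSE/SST with *uncentered*
SST = ΣM² — the muscle-synergy convention; a centered SST would change the
meaning of the 0.90 criterion. The module count N\* is the smallest N whose
VAF reaches 0.90, fitted in ascending order with optional early stopping
(the full curve over a range is available with `early_stop = FALSE`).
Module sets of successive sizes are related by Pearson correlation of their
temporal modules, with links above r = 0.7; the same threshold drives the
matching of modules across conditions (greedy one-to-one on decreasing r).

## Map segmentation and cluster statistics

Each column of A (optionally restricted to one task block) is mapped onto
the grid, masked channels set to NA. Segmentation is the two-step scheme:

1. rank-based histogram equalization over unmasked cells (ties share mean
   rank), then a marker-free watershed with 4-connectivity on the planar
   grid — cells are visited in decreasing height, a cell with no labelled
   neighbour seeds a basin (local maximum), otherwise it drains to its
   highest labelled neighbour;
2. within each basin, cells with values ≥ 70 % of the basin maximum form
   the activity cluster. Basins whose maximum falls below 10 % of the
   global maximum are discarded as noise — without a floor, flat noise maps
   would produce spurious clusters. If thresholding splits a basin, the
   4-connected component containing the basin peak is kept.

The grid is treated as planar (no circumferential wrap) for watershed, COG
and distances, matching how such maps are reported; distances are in grid
units, i.e. multiples of the IED. Cluster statistics: COG = weight-averaged
electrode position; overlap of two clusters = intersection size normalized
to the smaller and to the larger cluster (both reported, in %);
inter-condition COG shift = |x̄₁ − x̄₂| for matched modules; barycenter
weight = bilinear interpolation of the map at the COG (masked cells are
in-painted from 4-neighbour means first), and the prone/neutral weight
ratio divides the two barycenter weights. The effect of hand position on
COG coordinates is tested with a paired two-sided Wilcoxon signed-rank
test; for ≤ 25 non-zero differences the exact sign-flip distribution is
computed by convolution (mid-ranks for ties), since the standard
implementation falls back to a normal approximation whenever ties occur.

## Angle reconstruction

Two electrode subsets are compared: the full most-proximal grid row
(the "ring" of 14 electrodes nearest the elbow crease, y = 1) and one
unmasked electrode per activity cluster, nearest to the cluster COG (ties
toward lower x, then lower y; duplicates collapsed). How many electrodes
the targeted set should contain is not prescribed anywhere; one per
identified cluster is the documented choice.

Each joint gets a single-hidden-layer perceptron: 6 tanh units, linear
output, inputs z-scored with training-split statistics. Training is true
Levenberg–Marquardt (`minpack.lm::nls.lm` with an analytic Jacobian), run
in short bursts with early stopping on a validation split of 30 % of the
training cycles; the weights with the lowest validation error are kept.
Inputs are instantaneous envelope samples (the envelope's 1 Hz bandwidth
makes lagged windows redundant at these rates; the regression is run on
envelopes downsampled to 32 samples/s). Performance is r² under *cycle-wise*
four-fold cross-validation — folding by cycle rather than by sample avoids
leakage through envelope smoothness. Subsets are compared by one-way ANOVA
on the r² values followed by the Student–Newman–Keuls stepwise procedure on
the ordered means (studentized-range critical values per stretch size;
non-significant stretches protect their sub-stretches). SNK is implemented
in the package because no installed package provides it.

## Numerical choices and degenerate inputs

* Multiplicative updates stop when the relative SSE improvement over 10
  iterations falls below 1e-6 (max 400 iterations); a small epsilon guards
  the denominators. VAF is non-decreasing in N within 1e-6 by
  best-of-restarts.
* All-zero maps segment to an empty cluster list with a warning; zero
  total cluster weight, zero SST, constant regression targets and
  out-of-grid barycenters raise errors.
* Fewer than 2 onsets → "no cycles" error; > 60 % excluded cycles → task
  invalid; > 50 % bad channels → acquisition failure.
* Cycle counts: a task with n cycles yields n onsets and n − 1 complete
  cycles (the last onset closes the previous cycle).
* Fixed seeds make every stage bit-reproducible; `with_seed` restores the
  caller's RNG state, so library calls never perturb user randomness.

## Problem sizes used in the shipped analyses

Cohort-level analyses (module counts, separability, condition shifts,
acceptance checks) simulate 8 subjects with 10 movement cycles per wrist
condition and 8 cycles per finger task; single-subject repeatability checks
use the full 20-cycle wrist and 12-cycle finger protocol. These sizes are
the package's standing choice for cohort analyses: cycle-averaged envelopes
stabilize well below 10 cycles at the default jitter levels, and the
recovery medians are insensitive to doubling the cycle count.

## Known limitations

* The generator's envelope linearity (envelope ∝ spatial weight ×
  activation) holds exactly only for temporally non-overlapping sources;
  overlapping activations mix in RMS rather than amplitude, which slightly
  perturbs NNMF maps. The default sources keep overlap small.
* The watershed dialect (marker-free, 4-connected, drain-to-highest-
  neighbour) is one of several reasonable variants; on smooth unimodal maps
  they agree, on noisy multi-modal maps basin boundaries can differ.
* Synchronization between the kinematic and EMG streams is assumed exact
  (the generator provides aligned streams); aligning real hardware streams
  via a shared auxiliary channel is out of scope.
* Real-data effects (impedance drift, crosstalk, electrode shift within a
  session) are not modelled; quantitative thresholds tuned here (e.g. the
  10 % noise floor) may need revisiting for laboratory data.
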