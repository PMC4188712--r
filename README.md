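# emgmap

Spatial mapping of forearm muscle activity from high-density surface EMG
(sEMG) grids during cyclic wrist and finger movements.

## What it does

Multi-channel sEMG recorded with an electrode grid wrapped around the
forearm (here 14 columns x 8 rows, 15 mm inter-electrode distance, IED)
shows where on the limb each movement recruits muscle. `emgmap` implements
the complete analysis chain from raw monopolar grid signals and synchronized
joint-angle traces to quantitative activity maps:

* **Conditioning** — zero-phase 4th-order Butterworth band-pass (20–450 Hz),
  power-line removal by spectral interpolation (50 Hz and 4 harmonics),
  bad-channel detection, envelope extraction (rectify + 1 Hz zero-phase
  low-pass).
* **Movement cycles** — onset detection from the joint angle (2° rule over
  the extension-hold extremum), Tukey-fence rejection of range-of-motion
  outliers, time normalization of every cycle to 500 phase points, and
  envelope repeatability via the coefficient of multiple correlation (CMC).
* **Motor modules** — non-negative matrix factorization of the concatenated
  cycle-averaged envelopes, `M ≈ A·S`, with best-of-100-restarts fits, the
  module count selected as the least N with variance accounted for
  `VAF = 1 − SSE/SST ≥ 0.90` (uncentered SST), and similarity analysis of
  module sets of successive sizes (links at r > 0.7).
* **Activity clusters** — two-step segmentation of each spatial coefficient
  map (histogram equalization + marker-free 4-connected watershed, then a
  70 %-of-regional-max membership threshold), cluster centre of gravity
  `x̄ = Σ c_el·x_el / Σ c_el`, pairwise overlap normalized to the smaller and
  the larger cluster, inter-condition COG displacement in IED units,
  barycenter weights (bilinear) and prone/neutral weight ratios, with a
  paired exact Wilcoxon test on COG coordinates.
* **Angle reconstruction** — multilayer perceptrons (one hidden layer of 6
  tanh units, linear output, Levenberg–Marquardt training with early
  stopping) mapping envelope subsets to joint angles under cycle-wise
  four-fold cross-validation (r²), comparing a proximal ring of 14
  electrodes against one electrode per activity-cluster barycenter, with
  one-way ANOVA + Student–Newman–Keuls.

Since no recordings of this protocol are publicly deposited, the package
includes a first-class synthetic generator (`sim_config()`,
`simulate_emg()`, `simulate_kinematics()`) that plants Gaussian spatial
sources with temporal activation profiles, cycle-to-cycle variability,
20–450 Hz noise carriers, 50 Hz interference, dead electrodes and
trapezoidal joint-angle cycles — with full ground truth attached, so the
entire pipeline is validated by parameter recovery.

## Worked example

```r
library(emgmap)

# one synthetic subject: 3 planted sources, 10 wrist flexion/extension cycles
cfg  <- wrist_subject_config(seed = 1, n_cycles = 10)
rec  <- simulate_emg(cfg)                  # 112 channels x ~110 k samples
proc <- process_recording(rec)             # condition + cycles + envelopes

median_active_cmc(proc)
#> [1] 0.9907

mods <- subject_modules(proc, N = 3, n_restarts = 20, seed = 1)
round(mods$selection$vaf_curve, 4)
#>      1      2      3
#> 0.5176 0.8493 0.9963
mods$selection$N
#> [1] 3
```

The VAF curve says one or two modules cannot reconstruct the envelope maps
(52 %, 85 % of the pooled variation), while three do (99.6 %) — so the
module count N\* = 3 matches the three planted sources. The median CMC of
0.99 over active channels says the per-cycle envelopes are highly
repeatable at the generator's default variability (SNR 15 dB, 10 %
amplitude jitter).

Segmenting the spatial coefficient maps and comparing two simulated hand
positions recovers the planted condition effects; see
`analysis/01_simulate.R` … `analysis/06_angle_reconstruction.R` for the
complete narrative analyses (each writes its tables under `results/`).

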