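---
title: "Methods: wrist-worn gait detection, initial contacts and stride length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wrist-worn gait detection, initial contacts and stride length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristgait)
```

## The problem and the signal model

A wrist-worn IMU records triaxial acceleration at 100 Hz with an orientation
that changes freely as the arm moves. None of the axis-based conventions of
lower-back gait algorithms survive at the wrist, so every algorithm in this
package operates on the Euclidean norm of the acceleration vector — an
orientation-invariant scalar that carries gravity (about 1 g at rest), the
periodic arm-swing component at step frequency, and broadband heel-strike
transients. Three estimation tasks build on that signal:

1. **Gait-sequence detection (GSD)** segments a continuous recording into
   walking bouts. A bout is a stretch of gait containing at least two
   consecutive strides of both feet; pauses shorter than 3 s belong to the
   same bout, breaks of 3 s or more separate bouts. The 3 s boundary itself
   splits (merge strictly below 3 s) — the two textual clauses of the bout
   definition overlap at exactly 3 s and one side had to be chosen.
2. **Initial-contact detection (ICD)** places heel-strike timestamps inside
   externally supplied bouts (reference bouts during validation).
3. **Stride length (SL)** maps the norm between two consecutive initial
   contacts onto metres via intensity-based power laws — the only family of
   models available at the wrist, where inverted-pendulum double integration
   is not applicable.

All thresholds ship as data in `inst/extdata/parameters.yaml`, each tagged
with its unit. Most are in g; the adaptive Gu variance threshold is printed on
the (m/s²)² scale and is converted through the tag machinery rather than by
ad-hoc constants (`9.81` exactly, per the registry's own convention). The
canonical conversion helpers (`convert_unit()`, `param_value(..., as_unit=)`)
make a silent 9.81× error a type error instead.

## Preprocessing choices

* **Zero-phase filtering.** Every Butterworth stage is applied
  forward–backward unless a method demands causal use. Event *timing* is the
  deliverable; a causal fourth-order filter at gait frequencies would delay
  events by tens of milliseconds, which is the same order as the timing
  errors being measured. Mean removal plus odd-reflection padding (pad length
  scaled to the slowest cutoff) suppresses startup transients; a constant
  series passes through a low-pass exactly.
* **Resampling.** Rate changes (80, 50 and 128 Hz stages of Ducharme,
  McCamley and Pham) use a zero-phase Butterworth anti-alias filter at 0.45
  of the target rate followed by cubic-spline interpolation onto the new
  clock. A polyphase FIR resampler was rejected after measurement: the
  available implementation carries an uncompensated group delay of several
  samples, which would bias every resample-based IC detector by ~0.05 s.
* **Single-scale CWT.** The wavelet stage of McCamley, Pham and HKLee is a
  convolution with a Mexican-hat (second derivative of a Gaussian) kernel.
  The adaptive mode sets the scale so the wavelet's spectral peak
  (`sqrt(2)/(2*pi*sigma)`) matches the signal's dominant frequency in the
  0.5–3 Hz gait band; a flat signal has no dominant frequency and falls back
  to the fixed default scale (1.5 Hz center) with a warning.
* **Dominant frequency.** Welch periodogram: Hann window, segment length
  `min(N, 512)`, 50 % overlap, per-segment mean removal. Chosen over a raw
  periodogram for robustness on short bouts.

## Decisions where the printed descriptions were under-specified

The published method descriptions print thresholds but often not window
geometries or operational semantics. The package fixes these as follows (all
also visible in the registry or function documentation):

* **Hickey**: 1 s analysis windows at 0.1 s resolution; walking-candidate
  when the gravity-removed norm SD exceeds `thresholdstill` (0.1 g) and the
  raw norm stays below the `thresholdupright` activity ceiling (9.5 g), which
  excludes high-g shaking.
* **Kheirkhahan**: 1 s epochs, `win_size = 9` epochs with a 1-epoch hop. The
  activity *count* is defined as the epoch's peak-to-peak amplitude of the
  0.25–10 Hz band-passed norm — a per-epoch activity magnitude in g that is
  comparable to the printed 0.58 g threshold and robust across walking
  speeds. Only the central epoch of a passing window is marked, so the
  9-epoch smoothing does not smear bout edges; edge epochs use truncated
  windows.
* **MacLean**: the five printed constants are interpreted as: binarisation
  threshold (g), maximum fillable gap (s), minimum smoothed activity inside a
  fillable gap, minimum candidate duration (s), minimum raw activity fraction
  of a candidate. This is a declared interpretation, not published fact.
* **Keren**: 3 s windows, 50 % overlap, central half marked. Four criteria:
  at least 3 peaks above the amplitude threshold (fixed 0.08 g, or the 84th
  percentile of the window in the adaptive version), SD above 0.07 g,
  dominant frequency in 0.5–3 Hz, and an autocorrelation regularity floor of
  0.25 at the step-period lag. Because the spectral lag estimate is
  bin-quantized, regularity is taken as the autocorrelation maximum within
  ±30 % of that lag.
* **Ionescu**: gravity-removed norm low-passed at 3 Hz (cutoff not printed;
  chosen inside the gait band's upper harmonics), peaks at least 0.25 s
  apart. A run of steps breaks when an inter-step interval exceeds
  `min(3 s, 2.25 × running median step time)`. The adaptive version takes the
  31st percentile of candidate peak amplitudes (candidates above a 0.05 g
  floor) and falls back to 0.4 g when fewer than 10 candidates exist.
* **Iluz**: 1 s activity gating on the gravity-removed norm SD, 0.5–3 Hz
  band-pass, then normalized (Pearson) sliding correlation against a
  single-period sine template; `step_threshold = 0.84` is a correlation and
  is therefore dimensionless. The activity gate dominates: a periodic but
  tiny signal yields no bouts.
* **Minimum bout admission**: a detected bout must span at least four steps —
  step-based detectors count steps directly; window-based detectors apply a
  2 s minimum duration (four steps at a nominal 2 steps/s).
* **Shin**: 0.05 s sliding-window sum (noise reduction) followed by a 0.25 s
  lagged difference (the high-pass that removes gravity); initial contacts
  are the negative-to-positive zero crossings of the differenced signal,
  localised at the midpoint of the crossing with a small guard band against
  floating-point round-off.
* **Gu**: `period_min`/`period_max` are samples at 100 Hz (0.25–1.2 s step
  periods); similarity is the Pearson correlation of each peak neighbourhood
  (±0.2 s) with the mean neighbourhood, accepted at `sim_thres = -0.7`; the
  adaptive `mag_thres = 70` is the 70th percentile of the segment norm while
  the improved 1.1 is an absolute g threshold; continuity keeps runs of at
  least `k = 2` plausibly spaced peaks.
* **HKLee**: Savitzky–Golay window 21 / order 7 and Gaussian window 10 /
  σ = 2 (lineage defaults, nothing printed); morphological open–close with a
  0.05 s flat element; maxima between zero crossings with plateau ties
  resolved to the earliest sample.
* **Micó-Amigo**: step period from the autocovariance peak cross-checked
  against the spectral estimate; template averaged over step-period segments
  centred on prominent low-passed peaks spaced ≥ `peakdistance` (1.1 s);
  events are similarity-signal peaks spaced by `peakdistance_coef` step
  periods, screened by a DTW distance to the template (Sakoe–Chiba band
  `shiftfactor = 0.15` of the template length, rejection at `factorlimit = 2`
  times the median distance), and corrected by the fixed `event_offset`
  (5 samples) toward the contact.
* **Exponent readings (SL)**: the flattened typography `maxmin4`, `|mu|3`,
  `maxmin2.7` is implemented as the ¼, ⅓ and 1/2.7 roots, matching the cited
  source models (Weinberg fourth root, Kim cube root, Bylemans 2.7th root).
* **Foot length**: `B = foot length (cm)` is converted to metres before
  addition; adding centimetres to a metre-scale step would be dimensionally
  absurd and inconsistent with detected strides near 0.8 m.
* **Non-adaptive versions** drop the RMS factor; the printed equations with
  RMS describe the adaptive forms.
* **Physiological capping**: step estimates outside [0.1, 1.5] m are clamped
  and counted (`n_clamped`); the power laws explode on artefactual segments
  and the sources are silent on outlier handling.
* **Bout-level SL aggregation**: step values are interpolated to a per-second
  series (interval midpoints, linear interpolation, 1 s grid clipped to the
  bout) and the bout mean is the mean of that series; the alternative
  (per-stride mean) is a one-line change isolated in `assemble_strides()`.

## The synthetic generator: what it emulates and what it does not

`synth_walk()` builds the wrist norm's *statistical structure*, not its
biomechanics:

* gravity with a slow (0.02 Hz) norm-preserving orientation drift;
* an arm-swing fundamental at step frequency with a −45° phase (the swing
  maximum trails the initial contact by an eighth of a step period), a 10 %
  stride-frequency subharmonic for left/right structure, and small decaying
  cosine harmonics;
* a balanced biphasic heel-strike transient — a 25 ms deceleration dip 20 ms
  before the contact and an equal rebound spike 20 ms after. The balance
  keeps the jolt spectrally broadband: narrowband detectors lock to the
  fundamental while wideband minima/maxima detectors lock to the transient,
  both within a tenth of a second of the true contact, which mirrors the
  behaviour of these detectors on real wrist recordings;
* white noise per axis (default SD 0.02 g).

Amplitudes couple affinely to walking speed — swing `0.18 + 0.20·v` g and
impact `0.60 + 0.50·v` g — so intensity features carry speed information and
stride-length models can be tested for rank recovery. Ground truth is exact
by construction: initial contacts at the phase zeros of the fundamental with
alternating feet, inter-contact time exactly one step period, stride length
exactly speed × stride time.

The generator does **not** reproduce inverted-pendulum kinematics,
disease-specific asymmetry or variability phenotypes, sensor saturation, or
the amplitude statistics of any particular cohort. Consequently, passing the
synthetic battery demonstrates that each implementation detects the features
it claims to detect with correct timing and ranking behaviour — it does not
certify the printed thresholds against real data, and absolute stride-length
accuracy on the simulator (calibrated constants applied to synthetic
amplitudes) is biased even where rank order is perfect. Non-gait confounders
available for testing: 6 Hz-filtered noise bursts, 0.5 Hz arm waving, a
3.5 Hz tooth-brushing-like burst, and ≥10 g shaking (which exercises
Hickey's activity ceiling).

## Validation framework

* **Windows**: 0.1 s windows classified by *midpoint* membership
  (unambiguous at bout edges, conserves the window count); accuracy, recall,
  specificity and precision with zero-denominator ratios reported as
  undefined (`NA`), never 0.
* **Event matching**: one-to-one within ±0.25 s. Reference events take their
  nearest unmatched detection; when all candidates are taken the assignment
  is rearranged along an augmenting path, so the matching always reaches
  maximum cardinality (verified against an exhaustive oracle in the tests).
  Relative timing errors are normalised to each bout's mean reference step
  duration.
* **ICC(2,1)**: two-way random effects, absolute agreement, single measure,
  computed from the ANOVA mean squares; absolute agreement deliberately
  penalises systematic offsets.
* **Performance index**: weighted mean on [0, 1]. Benefits enter directly;
  costs are mapped through `exp(-cost/scale)`. The per-metric weights of the
  original framework are not published, so the default is uniform weights
  with per-cost scales set to acceptable magnitudes (50 % duration error,
  0.1 s absolute timing error, 15 % relative timing error, 0.2 m and 30 %
  stride error); both are configurable in `weight_config()` and every
  ranking records the weights used. Undefined metrics are excluded with
  weight renormalisation.
* **Trend analysis**: error versus walking speed or bout duration is fitted
  as `a·exp(-b·x) + c` by Levenberg–Marquardt least squares, reported with
  Pearson r and R² (clipped to [0, 1]); fewer than five bouts yields the
  scatter only.
* **Confidence intervals** are t-intervals across bouts/participants (the CI
  method is unstated in the sources).
* **Bland–Altman** differences are detector minus reference, so positive
  values mean overestimation.
* **Ranking**: descending performance index; ties break by accuracy (GSD),
  recall (ICD), ICC (SL), then name — deterministic by construction.

One terminology note: the registry implements the eight GSD versions of the
printed method table (six methods, two with adaptive variants); prose
references to "nine" GSD algorithms count differently and are not
reproducible from the table.

## Numerical choices and degenerate inputs

* A flat series raises a classed condition (`wg_flat_signal`) from
  `dominant_frequency()`; consumers either propagate it or fall back (CWT).
* Zero-crossing detectors use a guard band of `1e-8 × signal scale` so FFT
  round-off on constant input cannot fabricate events.
* Plateau maxima resolve to the earliest sample; peak pickers break height
  ties by earlier index — all detectors are bit-for-bit deterministic.
* Random number use is confined to the generator and always behind an
  explicit seed.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data: a
10-minute, 100 Hz recording with five walking bouts (50 % walking) for the
full GSD/ICD/SL battery, 30 s bouts across a six-speed sweep (0.4–1.6 m/s)
for stride-length rank recovery, five simulated participants for the
duration ICC, and 1000-instance randomized oracle checks for the discrete
operations. These sizes keep the whole suite under a minute of CPU while
leaving every code path exercised.

## Limitations

* The printed thresholds were calibrated on real multimorbid cohort data;
  this package takes them as given and does not re-tune them.
* Desk-scale validation is synthetic; absolute error levels on real wrist
  recordings cannot be inferred from it.
* No final-contact (toe-off) detection, no foot attribution from the wrist,
  no walking-speed/cadence outcomes beyond what stride assembly implies, and
  no machine-learning models.
* The reference JSON dialect is the package's own; adapters for proprietary
  multi-sensor exports are the user's single integration point
  (`read_imu_csv()`, `read_reference()`).
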