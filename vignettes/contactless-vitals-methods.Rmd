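---
title: "Methods: contactless heart-rate and blink-rate estimation and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contactless heart-rate and blink-rate estimation and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facevitals)
```

## What the package computes

`facevitals` implements two contactless estimators of neurophysiological
state from facial video, each paired with its laboratory reference:

* **Heart rate (HR)** from remote photoplethysmography (rPPG): the
  cardiac pulse modulates skin colour, visible as a small oscillation of
  the spatially averaged red channel over the cheeks. The reference is a
  single-lead ECG.
* **Eye-blink rate (EBR)** from the frame-by-frame eyelid distance
  measured on 68-point facial landmarks. The reference is the vertical
  EOG estimated from an Fpz electrode, where each blink produces a large
  corneo-retinal potential deflection.

A statistics layer quantifies device agreement the way validation
studies in this field do: baseline subtraction per subject,
Shapiro–Wilk-gated paired tests, repeated-measures correlation (rmcorr)
between per-minute estimates of the two technologies, and percentage
differences with the laboratory device as reference.

Because no recordings ship with the package, a synthetic-data module
generates every input with known ground truth, and all validation is
performed against that truth.

## Signal pipelines

### EBR from EOG (laboratory reference)

The 256 Hz trace is band-passed to 2–10 Hz with a 5th-order zero-phase
Butterworth. Detection is two-step:

1. **Threshold** from an eyes-open calibration segment:
   `mean + 3 × robustStdDev`, where the robust spread is the mean
   absolute deviation (a median-based estimator is available via the
   `estimator` argument but is not the default).
2. **Pattern matching**: every supra-threshold excursion is correlated
   against a blink template; candidates with Pearson r > 0.9 become
   events, separated by a 200 ms refractory period.

The template's shape is not standardised anywhere, so the package uses a
300 ms raised-cosine (Hann) bump — vertical-EOG blink deflections are
smooth monophasic bumps of roughly that width. Two implementation points
matter:

* The **template is passed through the same 2–10 Hz filter** before
  correlating. The filter turns the monophasic bump into a biphasic
  waveform with pronounced negative side lobes; correlating the filtered
  signal against the *raw* bump compares unlike shapes and lets
  band-limited noise through the 0.9 gate.
* The correlation segment spans ±0.35 s around the excursion maximum,
  covering the full ringing support. Shorter segments have too few
  effective degrees of freedom: band-passed noise (correlation time
  ≈ 0.1 s at 2–10 Hz) then matches the template by chance often enough
  to produce false positives.

### HR from ECG (laboratory reference)

1–4 Hz 5th-order zero-phase Butterworth, then pointwise cubing to
emphasise the QRS complexes, then peak picking, then
`bpm = 60 / mean(RR)` per non-overlapping 60 s window (windows holding
fewer than two beats are flagged invalid; a partial trailing window
reports its true duration).

Decisions the method statement leaves open, and how they were resolved:

* **Adaptive threshold**: 0.2 × the rolling 95th percentile of the cubed
  signal over 10 s segments. The threshold is scale-free and tracks
  amplitude drift. The fraction must be read on the cubed scale: a
  fraction *f* admits beats whose filtered lobe droops to *f*^(1/3) of
  typical. At high heart rates adjacent beats' 1–4 Hz lobes interfere
  and individual beats routinely droop to ~30 % of the median cubed
  amplitude, so the fraction has to sit well below that on the cubed
  scale (0.2 → tolerates 42 % amplitude droop) while remaining orders
  of magnitude above the cubed noise floor.
* **Polarity**: cubing preserves sign, so an inverted lead would hide
  its R peaks; polarity is auto-detected from the skewness of the cubed
  signal and flipped when negative.
* **Peak timing**: the 1–4 Hz band-pass suppresses the narrow R spike
  relative to the broad T lobe, so the cubed maximum lags the true R
  peak by ~0.25 s. Each detected peak is therefore refined to the
  largest-magnitude raw sample in an asymmetric window (0.3 s back,
  0.05 s forward). Constant lags cancel in RR intervals, but they move
  beats across window boundaries; with the refinement, window HR values
  agree with truth-derived values to well under 1 bpm.

### EBR from video

Per frame, the eyelid distance is the mean over both eyes of the two
vertical lid-landmark pair distances of the standard 68-point eye
hexagon; invalid frames are linearly interpolated and flagged. The trace
is band-passed to 1–3 Hz, a threshold is set at the quadratic mean (RMS)
of the filtered condition, and threshold-exceeding events are counted.

This simple rule needs four qualifications to count correctly, all
driven by the physics of the filtered trace:

* **Signed detection.** A blink *closes* the eye: the filtered trace
  swings negative first. Thresholding the closure direction (`−x`)
  rather than `|x|` matters because the zero-phase band-pass rings: one
  blink produces a −/+/− lobe triplet whose rectified side lobes each
  cross the RMS threshold ~0.2 s apart, so rectified detection counts
  every blink two or three times.
* **Filter order 2.** The 1–3 Hz band is only two octaves wide. At
  order 5 the same-sign ringing lobes reach 16 % of the main lobe and
  at sparse blink rates exceed the RMS threshold; at order 2 they are
  7 % and separate cleanly from genuine events. (The order of this
  particular band is not standardised; orders quoted for the biosignal
  filters are 5 and remain 5 here.)
* **A robust noise floor.** With sparse blinks the RMS threshold sits
  only ~2 standard deviations above the filtered noise, and bare
  RMS-thresholding over-counts by several events per minute. Events
  must additionally clear 4.6 × a robust noise scale, estimated as the
  lower-half MAD of the trace after masking ±0.9 s around clearly
  supra-threshold events (blink mass is one-sided in the closure
  direction, so the lower half of the distribution is nearly
  contamination-free; masking avoids the residual ring lobes). The
  multiplier comes from Gaussian crossing statistics — at 4.6 σ the
  expected number of spurious events per one-minute trace is ~10⁻³ —
  not from fitting any benchmark.
* **Structural gates.** Excursions containing two distinct blink
  responses are split at valleys dropping below half the smaller
  adjacent peak (a plateau stays one event); ringing side lobes are
  removed by requiring each event to reach 35 % of the largest event
  within ±1 s (facing lobes of two large neighbours sum to ~24 % plus
  noise, while a genuine small blink next to a large one stays ≥ 39 %
  even at 5 dB); and a 200 ms refractory period prunes the remainder.
  Events inside the filter's ~3 s settling region at the trace edges
  are discarded.

### HR from video (rPPG)

The stage order is: cheek ROIs → PCA → detrending → band-pass → z-score
→ windowed spectral peak.

* **ROI extraction.** Cheek rectangles referenced to the eye centres and
  the nose-tip column, sized in proportion to the inter-ocular distance
  (width 0.45, height 0.35, vertical drop 0.25 — fractions chosen to
  cover the malar skin patch while avoiding eyes, nose and mouth for
  typical frontal geometry). Per frame and ROI, each channel's spatial
  mean is recorded; only the red channel continues down the pipeline.
* **PCA cleanup.** Principal components of the standardised left/right
  red traces. The pulse is common to both cheeks while sensor noise is
  not, so the component with the greatest in-band (0.6–2.2 Hz) to
  out-of-band power ratio is selected, sign-aligned with the mean red
  trace. Frequencies below 0.25 Hz are excluded from the out-of-band
  mass: illumination drift is removed by the dedicated next stage, and
  counting it against a component that carries both drift and pulse
  would systematically select the noise component instead.
* **Smoothness-priors detrending.** The trend is
  `(I + λ²·D₂ᵀD₂)⁻¹·x` with `D₂` the second-difference operator, solved
  sparsely (banded Cholesky plus one step of iterative refinement; the
  system's condition number grows as 16λ²). The detrender is a
  high-pass whose half-power cutoff is ≈ `fs/(2π√λ)`. The package
  derives λ from the stated drift cutoff of 0.060 Hz at the trace's
  sampling rate — λ ≈ 6 300 at 30 fps — rather than fixing λ = 10: at
  30 fps, λ = 10 puts the half-power point near 1.5 Hz, which
  attenuates a 48-bpm fundamental to 7 % gain while passing its second
  harmonic at 55 %, guaranteeing harmonic confusion at the low end of
  the cardiac band. A fixed λ remains available via
  `detrend_spec(lambda =)`.
* **Band-pass**: 128-tap Hamming-window FIR, 0.6–2.2 Hz (36–132 bpm),
  applied zero-phase like every filter in the package.
* **z-score**: population-SD normalisation; constant input returns
  zeros with a degenerate flag.
* **Spectral peak.** Per 100-frame sliding window (hop 1 s), HR is 60 ×
  the argmax of the zero-padded (n_fft = 4096) power spectrum within
  0.6–2.2 Hz, refined by 3-point parabolic interpolation on log power.
  The raw resolution of a 3.3 s window is 18 bpm, so the padding and
  interpolation are what make the estimate usable. A Hann taper is
  applied to the window first: at ~4 cardiac cycles per window, leakage
  from the negative-frequency image otherwise biases the interpolated
  peak by several tenths of a bpm in a frequency-dependent (hence
  systematic) way. Windows are flagged invalid when the in-band argmax
  sits on a band edge or lacks 5× prominence over the median in-band
  power. The per-minute value is the median of the valid window
  estimates starting in that minute (invalid if fewer than half are
  valid); windows overlapping the FIR's settling region are skipped.

## Statistics layer

* `baseline_normalize`: plain subtraction of the subject's resting
  baseline.
* `paired_compare`: Shapiro–Wilk on the paired differences (the
  quantity the t-test assumes normal) gates between the paired t-test
  and the Wilcoxon signed-rank test at α = 0.05. The signed-rank test
  is implemented in-package: exact two-sided p by dynamic programming
  over achievable rank sums for n ≤ 25 (valid under midranks/ties),
  normal approximation with continuity and tie corrections above. No
  multiple-testing correction is applied — each task/metric pair is
  tested separately at α = 0.05.
* `rmcorr`: the ANCOVA formulation with subject-specific intercepts and
  a common slope, computed as the Pearson correlation of the
  within-subject centred variables, `dof = N_obs − N_subjects − 1`, and
  `p` from the t transform. Subjects with constant x contribute no
  slope information.
* `percent_difference`: mean over subjects of |video − lab| / |lab| ×
  100, with the laboratory device as denominator (it is the reference
  being validated against; pairs with a zero laboratory value are
  excluded with a warning).

## The synthetic-data generators

The generators define the study conditions; every validation statement
in the package is a statement about these conditions.

* **ECG** (256 Hz): a QRS-like kernel (narrow biphasic R spike, smaller
  P and T bumps) placed at `RR = 60/hr` with ±3 % beat-to-beat jitter;
  stepwise per-minute heart-rate profiles are supported.
* **EOG** (256 Hz): positive 300 ms Hann-bump deflections at
  Poisson-thinned times with a 500 ms minimum inter-blink interval,
  over Gaussian baseline noise. A blink-free eyes-open calibration
  segment with the identical noise level is emitted alongside.
* **Eyelid distance** (30 fps): 6 px open-eye baseline with downward
  Hann closures of 0.2–0.35 s and 4 px depth, plus frame-to-frame
  landmark jitter.
* **Cheek ROI traces** (30 fps): red = base + pulse (sinusoid plus a
  30 % second harmonic, so the spectral picker is exercised against
  harmonic confusion) + common low-frequency drift (three random tones
  in 0.02–0.1 Hz) + independent per-cheek noise; green/blue carry base,
  drift and noise only.

**SNR convention.** `snr_db` is the ratio of clean physiological
component power to noise power over the trace. For event-type signals
(blinks) the noise level is referenced to the *expected* component
power at the requested event rate, computed analytically — a
realisation that happens to contain few or no blinks still receives the
same noise floor. At the default blink morphology, 10 dB corresponds to
roughly 0.1 px RMS landmark jitter on a 4 px closure — clean but
realistic tracking; 5 dB is visibly noisy tracking.

All generators are deterministic under a fixed seed (and restore the
session RNG state on exit). Each returns its ground truth alongside the
data, so any pipeline test is self-scoring. Recordings include a 4 s
event-free lead-in/lead-out: the recording starts before the condition
does, which both mirrors acquisition practice and keeps filter
transients away from events. The generators emulate trace-level
physics only — no rendered video frames, no head motion, no gaze or
lighting dynamics, no non-Gaussian artifact bursts. Passing recovery
tests on these conditions demonstrates the correctness and noise
robustness of the signal processing, not performance on arbitrary
real-world video.

## The virtual agreement study

`agreement_study()` re-creates the structure of a device-validation
experiment on synthetic participants: 15 virtual subjects × (baseline,
nominal = rest, non-nominal = active) × both technologies, with the
*same* physiological truth per subject/condition driving the laboratory
and the video recording (shared blink times; shared per-minute HR
profile) and independent sensor noise in each modality. Engagement
lowers EBR by 4–8 blinks/min and raises HR by 5–10 bpm — the usual
directions for cognitive load. Heart rate follows a ±2 bpm/min random
walk so the per-minute rmcorr has within-subject variance to correlate.
Conditions last 120 s, baselines 60 s, at 15 dB recording quality.

The study's paired method-agreement tests are true null hypotheses by
construction (both modalities estimate the same truth with independent
errors), so their p-values are uniform: a fixed seed realises one draw
from that distribution, and any single draw has the usual 5 % tail
risk per test. The packaged tests use the package-wide default seed.

## Numerical and edge-case behaviour

* All filtering is offline zero-phase (forward–backward); IIR filters
  are designed in zero-pole form from the analog prototype and applied
  as cascaded biquads — the expanded transfer function of a 5th-order
  band-pass at 256 Hz with a 1–4 Hz band is numerically unstable
  (poles leave the unit circle under coefficient rounding).
* The signal mean is removed before filtering, making DC rejection
  exact rather than limited by the FIR's −53 dB stopband floor.
* Every filtered signal carries a `transient_samples` attribute
  (from the slowest pole's decay, or taps − 1 for FIR); downstream
  thresholding and windowing exclude those regions.
* Degenerate inputs are flagged, not propagated: constant signals
  z-score to zeros with a flag, flat ECG yields an empty peak train
  with a warning, all-zero paired differences give p = 1 with a
  degenerate flag, an all-invalid HR minute is flagged invalid.
* Ties in peak pruning resolve by amplitude, largest first; exact ties
  in the Wilcoxon are handled by midranks in the exact enumeration.

## Validation scale and known limitations

The packaged validation (tests and `scripts/acceptance.R`) runs, per
pipeline: 5 levels × 20 seeds × 120 s recordings for both HR pipelines;
5 rates × 50 seeds × 2 SNRs for video EBR; 100 recordings for EOG EBR;
oracle comparisons at N up to 2000 (detrending) and 50 random designs
(rmcorr); and one 15-subject virtual study. These sizes give stable
summary statistics (binomial SE ≈ 0.6 % on the exact-count fraction)
while keeping a full run around a minute.

Known limitations: no motion compensation or skin segmentation in the
rPPG path (and no chrominance-model variants such as CHROM/POS); no
per-eye disagreement rejection in the blink path; the landmark detector
itself is out of scope (any callable producing 68-point frames can be
plugged in); EBR accuracy at 5 dB has an irreducible noise-tail risk of
±2 miscounts in a small fraction of one-minute traces; and synthetic
validation bounds real-world performance only to the extent the
generators' assumptions (stationary noise, frontal face, stable
illumination geometry) hold.
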