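---
title: "Pulse-wave HRV screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-wave HRV screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pulsescreen)
```

## The screening idea

Major depressive disorder is associated with blunted autonomic *transient*
responses: when a healthy person performs a brief stressor (here, vocalizing
a random digit every second for 100 s), heart rate rises and vagally
mediated heart-rate variability (HRV) drops, then both recover; in many
depressed patients this transient is attenuated or delayed. The screening
method quantifies the transient from a fingertip photoplethysmographic
(PPG) pulse recording — no electrodes, no clinical supervision — over a
320-s protocol: 100 s seated rest, 100 s mental task, 120 s rest.

Three autonomic indices are tracked through time: heart rate (HR, bpm),
high-frequency HRV band power (HF, 0.15–0.4 Hz, in ms², a parasympathetic
index) and the LF/HF ratio (LF: 0.04–0.15 Hz, a sympathovagal balance
proxy). Averaging each index over each protocol phase gives nine features
$X_{ji}$ ($j$ = before/during/after, $i$ = HR/HF/LF/HF), combined linearly
into a screening score

$$\mathrm{logit} = \sum_{i,j} A_{ij} X_{ji} + \mathrm{constant},$$

with higher scores indicating the healthy group. The package ships the
published coefficient matrix as a frozen model (`reference_model()`), a
ridge-stabilised trainer for refitting (`fit_logistic()`), and
leave-one-out cross-validation (`loocv_evaluate()`).

## Pipeline stages and their numerical choices

### Peak detection (`detect_pulse_peaks`)

The raw waveform is detrended with a 1-s moving average, smoothed with a
50-ms moving average for candidate finding, thresholded at a rolling 80th
amplitude percentile (10-s window), and scanned for local maxima with a
300-ms refractory period (a 200-bpm physiological ceiling). Candidate peaks
are refined in a second, adaptive-template pass: all detected pulses are
ensemble-averaged into an empirical template, whose apex is located on a
dense spline grid, and every beat is re-aligned by the cross-correlation
maximum between its raw segment and the template. The correlation peak is
the key: the autocorrelation of *any* pulse shape is symmetric about zero
lag, so this alignment carries none of the systematic late bias that plain
parabolic apex interpolation suffers on pulses with a fast systolic rise
and a slow, flat decay — on such pulses, at 20 dB SNR, apex interpolation
alone left a median error of about 8 ms and a long late tail, while the
template pass brings every beat within 7 ms of truth. The plain parabolic
path remains available (`template_refine = FALSE`).

The detector is invariant to waveform gain and constant offset, and the
per-beat estimate depends only on local signal shape, so amplitude drift
does not propagate into intervals.

### Interval cleaning (`clean_intervals`)

Peak-to-peak intervals outside [300, 2000] ms, or deviating more than 25%
from the running 5-point median, are flagged and replaced by linear
interpolation over clean neighbours; a recording with more than 20% flagged
intervals is rejected outright. These gates follow common HRV
pre-processing practice and are fully configurable; small interval
artifacts matter because their broadband energy bleeds straight into HF
and LF/HF.

### Spectral HRV (`resample_tachogram`, `band_powers`, `sliding_hrv`)

The irregular interval series is interpolated with a natural cubic spline
(the standard HRV choice for "polynomial" tachogram interpolation) and
resampled at 4 Hz. Sliding 30-s windows, advanced in 2-s steps, are
mean-removed, Hann-windowed and transformed with a 120-point DFT — no zero
padding, so the bin width is exactly 1/30 Hz and the band edges fall
between bins. Bands are half-open, LF = (0.04, 0.15] Hz and
HF = (0.15, 0.4] Hz, so the shared 0.15-Hz edge can never be counted
twice. Per-bin powers are normalized by the Hann window's power loss so
that a pure in-band sinusoid of amplitude $A$ ms contributes band power
$A^2/2$ ms² — a contract that makes the window choice testable and
swappable. Each window is stamped at its center (symmetric latency around
transients); windows are attributed to protocol phases by that center.

Two consequences of this design are worth knowing. First, spectral
leakage: a tone needs to sit roughly 0.03 Hz inside a band for 95% of its
power to land there; tones within ~0.025 Hz of the 0.15-Hz edge split
across both bands (the Hann main lobe is about ±2 bins wide). Second, the
window HR estimate is `60000 / mean(pp_ms)` over intervals anchored in the
window — the harmonic-mean convention, chosen and documented because the
estimator behind published per-phase HR values is never stated.

When the pipeline analyses a full recording it builds the tachogram over
the recording extent `[0, 320]` s rather than the anchor span, so that a
320-s recording always yields 146 windows centered at 15, 17, …, 305 s
(43/50/53 per phase); the sub-second extrapolation at the edges uses the
spline's natural linear tails.

### Screening model and training (`fit_logistic`, `loocv_evaluate`)

The frozen reference model is used exactly as published — no feature
standardization, no transformation — because its heterogeneous coefficient
magnitudes are only consistent with raw-scale features. Scores at or below
the threshold (default 0, i.e. probability one half) are labeled MDD, the
positive screening class; the threshold is exposed because no published
value exists.

Training maximizes the binomial log-likelihood (healthy coded 1) with a
ridge penalty $\lambda\sum \beta^2$ on the slopes only, $\lambda=10^{-8}$
by default: with ~20 subjects and 9 features the classes are typically
linearly separable and the unpenalized MLE diverges; the tiny ridge merely
stabilizes it. Newton iterations with step-halving converge when the
penalized log-likelihood changes by less than $10^{-8}$ (cap 100
iterations); the fit is deterministic. On non-separable data the fitted
coefficients agree with `glm()`'s MLE to ~1e-5 relative; at n = 5000 a
known 9-coefficient generating model is recovered within 10% per
coefficient. Leave-one-out evaluation refits on every size-(n−1) subset
and aggregates a confusion matrix with MDD as the positive class.

### Validation statistics

`paired_agreement()` gives the Pearson correlation with the usual
t-transform p-value. As a structural property, HR series derived from a
pulse stream and from its transit-delayed reference (ECG-like) stream are
identical when each stream is windowed on its own timeline — the intervals
are untouched by a constant delay — which the suite asserts at r = 1 to
1e-12.

`group_difference_tests()` reports *unpaired* two-sample tests (Student
and Welch) even though tables of this design are sometimes labeled
"paired": with independent groups of unequal size, pairing is impossible.
The variance-ratio F convention (which group's variance is the numerator)
is unstated in published tables and not exactly recoverable from rounded
SDs, so it is configurable; the default puts the healthy variance in the
numerator.

`quantile_residual_diagnostics()` draws, for each subject, a uniform
variate on the Bernoulli CDF jump of the observed outcome and maps it
through the standard-normal quantile. Under a correctly specified model
these randomized quantile residuals are *exactly* standard normal, so the
Anderson–Darling test is applied in its fully specified (case-0) form —
no mean or SD estimated — with Marsaglia's asymptotic approximation for
the p-value. Published residual analyses of this kind sometimes use the
estimated-parameter variant instead; the case-0 form is the principled
choice here and is calibrated (5%-level rejection rate 5% ± 2% at
n = 500 over 500 replicates). Whether diagnostics should use the training
fit or held-out probabilities is genuinely open; the default is the
training fit, and any model object can be passed.

## The synthetic generator: what it emulates, and what it does not

`simulate_beat_series()` uses integral pulse frequency modulation (IPFM):
beat $k$ fires when $\int_0^t (1+m(s))/T_0(s)\,ds$ reaches $k$, where
$T_0$ is the phase's mean beat period and $m$ is one LF plus one HF
sinusoid with seeded random initial phases. IPFM is the standard HRV
simulation model because it makes band powers controllable: a modulation
amplitude $a$ produces tachogram oscillations of amplitude
$\approx a\,T_0$ ms and hence band power $\approx (a\,T_0)^2/2$ ms².
`modulation_from_features()` inverts that relationship so a synthetic
subject can be built directly from per-phase HR / HF / LF/HF targets.
Phase parameters switch instantaneously at boundaries, matching an
instantaneous task onset.

`render_ppg_waveform()` superposes an asymmetric raised-cosine pulse
(100-ms rise, 250-ms decay — qualitatively the fingertip pulse shape; the
exact shape is irrelevant to intervals) at each beat and emulates the
acquisition chain: 100-Hz sampling, 12-bit quantization, optional baseline
drift and white noise at a configured SNR. `derive_reference_beats()`
shifts beats earlier by the pulse transit delay (default 300 ms) to create
the paired ECG-like stream.

`simulate_feature_cohort()` draws labeled nine-feature subjects from
per-group Gaussians — defaults for the clinical condition come from
`reference_group_params()`, the published group means and SDs for 6 MDD
and 14 healthy participants. HF and LF/HF cells are resampled until
positive, since several published SDs exceed their means; truncation
necessarily shifts those cells' realized moments upward, which is accepted
and documented. One published cell (healthy LF/HF after the task) is
corrupted in print — only its SD, 1, is legible — so the function requires
that mean explicitly and invents no default; examples in this package pass
1.5, a value between the healthy before-task (1.3) and during-task (5)
means, flagged as a synthetic choice wherever it appears.

What the generator does **not** emulate: respiration–cardiac coupling,
baroreflex feedback, ectopy and arrhythmia, motion artifacts, sensor
saturation, or any correlation between the nine features beyond an
optional user-supplied correlation matrix. Tests passing on this generator
therefore demonstrate the *pipeline's* correctness — detection accuracy,
spectral calibration, estimator contracts, training and evaluation logic —
not clinical screening performance on real patients. The published
clinical accuracies (83% sensitivity, 93% specificity on 20 participants)
depend on raw recordings that are not available and are deliberately not
reproduced.

## Problem sizes used by the test-suite and acceptance script

Chosen to exercise every contract at meaningful scale while keeping a full
run around a quarter of a minute for the suite and a few seconds for the
acceptance script: 300–320-s single recordings at 100 Hz for detection and
the end-to-end pipeline; 100 random segments for the spectral oracle;
cohorts of 6 + 14 (the clinical sizes) for LOOCV; n = 5000 for parameter
recovery; 500 replicates of n = 500 for residual-test calibration.

## Known limitations

* The detector's adaptive template assumes one dominant pulse morphology
  per recording; a recording with abrupt morphology changes would blur the
  template (alignment degrades gracefully toward the plain parabolic
  estimate).
* Band powers use a single fixed 30-s Hann window; no multitaper or
  autoregressive option, no VLF band, no time-domain indices — out of
  scope by design.
* The ridge trainer reproduces the *kind* of stabilization used by the
  original training software; whether that tool applied internal
  normalization when the published coefficients were produced is
  unknowable, so refitting on new data and the frozen model are kept as
  clearly separate code paths.
* `classify()` ties go to MDD (the positive class) by documented
  convention.
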