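# pulsescreen

Heart-rate-variability screening for major depressive disorder (MDD) from a
fingertip pulse wave, implemented as a tested, reusable R pipeline.

Depression blunts the autonomic *transient* response to a brief mental
stressor. This package quantifies that transient from a fingertip
photoplethysmographic (PPG) recording taken over a 320-s protocol — 100 s
rest, 100 s mental task (vocalizing a random digit each second), 120 s
rest — and turns it into a screening score:

1. **Pulse processing** — systolic peak detection (adaptive threshold +
   ensemble-template re-alignment), peak-to-peak (PP) intervals, artifact
   gating and repair.
2. **Spectral HRV** — natural-cubic-spline tachogram resampled at 4 Hz;
   sliding 30-s Hann-windowed 120-point DFTs every 2 s; band powers
   HF = (0.15, 0.4] Hz and LF = (0.04, 0.15] Hz in ms², normalized so an
   in-band sinusoid of amplitude *A* yields *A*²/2.
3. **Screening score** — phase averages of HR, HF and LF/HF form nine
   features *X<sub>ji</sub>* (j = before/during/after, i = HR/HF/LF/HF),
   combined as

   logit = Σ<sub>ij</sub> A<sub>ij</sub> X<sub>ji</sub> + constant,

   with the published frozen coefficient matrix shipped as
   `reference_model()` (constant 605.15; higher score ⇒ healthy).
4. **Training & evaluation** — ridge-stabilised maximum-likelihood
   logistic fitting (`fit_logistic()`, λ = 1e-8 on slopes) and
   leave-one-out cross-validation with sensitivity/specificity (MDD =
   positive class).
5. **Validation statistics** — paired-method Pearson agreement, per-variable
   unpaired t/F group tests, and randomized quantile residual diagnostics
   with a fully specified Anderson–Darling normality test.
6. **Synthetic signals** — an integral-pulse-frequency-modulation (IPFM)
   beat simulator with per-phase LF/HF modulation, a 100-Hz/12-bit pulse
   waveform renderer, a transit-delayed ECG-like reference stream, and a
   nine-feature cohort simulator seeded with the published clinical group
   statistics — so the whole pipeline runs and is tested without hardware
   or patient data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on waveforms, HRV series,
screening results and residual diagnostics.

## Worked example

Simulate a healthy-profile 320-s recording, run the full pipeline, then
screen a synthetic 6 + 14 cohort by leave-one-out cross-validation. (The
healthy after-task LF/HF group mean is not legible in the published table,
so `reference_group_params()` requires it explicitly; 1.5 is this
package's documented synthetic choice.)

```r
library(pulsescreen)

cfg <- modulation_from_features(hr = c(73.8, 77.8, 70),
                                hf_ms2 = c(365.9, 109.9, 334.4),
                                lfhf = c(1.3, 5, 1.5), seed = 1)
beats <- simulate_beat_series(cfg)
wav <- render_ppg_waveform(beats, noise_snr_db = 25, duration_s = 320,
                           seed = 2)
run <- run_screening_pipeline(waveform = wav)
print(run)
#> Screening run: 392 beats, 146 HRV windows, logit score -1765.296 -> MDD
```

392 detected beats become 146 sliding spectral windows (centers 15, 17, …,
305 s; 43/50/53 per phase); their phase averages reproduce the configured
autonomic profile:

```r
run$features  # rounded
#> hr 74.0 / 77.4 / 70.3 bpm; HF 320 / 113 / 307 ms^2; LF/HF 1.54 / 5.29 / 1.75
```

(The frozen model maps published group-mean-scale features to large
negative logits; the decision threshold of 0 still separates groups, which
is what the cross-validated evaluation measures.)

```r
params <- reference_group_params(healthy_lfhf_after_mean = 1.5)
cohort <- simulate_feature_cohort(params, 6, 14, seed = 3)
res <- loocv_evaluate(cohort)
print(res)
#> Screening result (n = 20, threshold = 0)
#>          predicted
#> truth     MDD healthy
#>   MDD       6       2
#>   healthy   0      12
#> sensitivity = 1.000, specificity = 0.857
```

Each subject was held out once, the model refit on the remaining 19, and
the held-out subject scored: on this draw all 6 MDD subjects screen
positive (sensitivity 1.00) and 12 of 14 healthy subjects screen negative
(specificity 0.86).

## Scope

Clinical recruitment, DSM-based diagnosis, questionnaire comparisons,
sensor electronics and smartphone interfaces are out of scope, as is any
claim about screening accuracy on real patients: the published clinical
accuracies were computed on 20 participants whose raw recordings are not
available. See the methods vignette (`vignettes/screening-methods.Rmd`)
for the models, parameter choices and their rationale.
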