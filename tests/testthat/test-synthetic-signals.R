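test_that("unmodulated integrate-and-fire is an exact metronome", {
  cfg <- modulation_config(modulation_phase(60, 75), seed = 1)
  beats <- simulate_beat_series(cfg)
  expect_equal(beats$beat_time_s, 0.8 * seq_len(nrow(beats)),
               tolerance = 1e-9)
  expect_true(all(diff(beats$beat_time_s) > 0))

  # realized mean HR stays within 1 bpm of the configured rate even under
  # strong modulation
  cfg2 <- modulation_config(
    modulation_phase(120, 75, lf_amp = 0.15, hf_amp = 0.15), seed = 2)
  b2 <- simulate_beat_series(cfg2)
  hr <- 60 / mean(diff(b2$beat_time_s))
  expect_lt(abs(hr - 75), 1)
})

test_that("beat simulation is deterministic and seed-driven", {
  cfg <- modulation_config(
    modulation_phase(80, 70, lf_amp = 0.05, hf_amp = 0.05), seed = 7)
  expect_identical(simulate_beat_series(cfg), simulate_beat_series(cfg))
  # fixed phases: the seed becomes irrelevant
  mk <- function(seed) modulation_config(
    modulation_phase(80, 70, lf_amp = 0.05, hf_amp = 0.05),
    seed = seed, lf_phase = 0.4, hf_phase = 1.1)
  expect_identical(simulate_beat_series(mk(1)), simulate_beat_series(mk(99)))
  # different seeds draw different phases
  cfg_b <- modulation_config(
    modulation_phase(80, 70, lf_amp = 0.05, hf_amp = 0.05), seed = 8)
  expect_false(isTRUE(all.equal(simulate_beat_series(cfg)$beat_time_s,
                                simulate_beat_series(cfg_b)$beat_time_s)))
})

test_that("modulation configs reject non-physiological parameters", {
  expect_error(modulation_config(modulation_phase(60, 75, lf_amp = 0.6,
                                                  hf_amp = 0.5)),
               "non-positive")
  expect_error(modulation_config(modulation_phase(-5, 75)), "duration")
  expect_error(modulation_config(modulation_phase(60, 250)), "mean_hr")
  expect_error(modulation_config(modulation_phase(60, 75, hf_freq = 0.5)),
               "hf_freq")
  expect_error(modulation_config(modulation_phase(60, 75, lf_freq = 0.3)),
               "lf_freq")
})

test_that("HF modulation amplitude maps monotonically onto HF band power", {
  hf_power <- function(amp) {
    cfg <- modulation_config(
      modulation_phase(100, 75, lf_amp = 0, hf_amp = amp, hf_freq = 0.25),
      lf_phase = 0, hf_phase = 0)
    beats <- simulate_beat_series(cfg)
    iv <- beats_to_intervals(beats)
    hrv <- sliding_hrv(resample_tachogram(iv), iv)
    c(hf = median(hrv$hf_ms2), lf = median(hrv$lf_ms2))
  }
  base <- hf_power(0)
  p1 <- hf_power(0.01)
  p2 <- hf_power(0.02)
  p4 <- hf_power(0.04)
  expect_true(p1["hf"] < p2["hf"] && p2["hf"] < p4["hf"])
  # doubling the amplitude at least doubles the baseline-corrected power
  expect_gte(p2["hf"] - base["hf"], 2 * (p1["hf"] - base["hf"]))
  expect_gte(p4["hf"] - base["hf"], 2 * (p2["hf"] - base["hf"]))
  # pure HF modulation concentrates in the HF band
  expect_gte(p2["hf"] / (p2["hf"] + p2["lf"]), 0.95)
})

test_that("rendered waveform has one clean peak per beat, quantized levels", {
  cfg <- modulation_config(modulation_phase(60, 75), seed = 3)
  beats <- simulate_beat_series(cfg)
  wav <- render_ppg_waveform(beats, quantization_bits = 12)
  expect_lte(length(unique(wav$amplitude)), 4096)
  expect_equal(attr(wav, "fs_hz"), 100)
  # per-pulse argmax lands within half a rise time of the beat
  for (b in beats$beat_time_s[2:11]) {
    sel <- wav$time_s >= b - 0.3 & wav$time_s <= b + 0.3
    tpk <- wav$time_s[sel][which.max(wav$amplitude[sel])]
    expect_lt(abs(tpk - b), 0.05)
  }
  # count of local maxima at pulse scale equals the number of beats
  x <- wav$amplitude
  n <- length(x)
  peaks <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                   x[2:(n - 1)] > max(x) / 2) + 1
  groups <- cumsum(c(1, diff(wav$time_s[peaks]) > 0.3))
  expect_equal(length(unique(groups)), nrow(beats))
  # merging pulses are refused
  fast <- tibble::tibble(beat_time_s = seq(0, 5, by = 0.3))
  expect_error(render_ppg_waveform(fast, rise_s = 0.15, decay_s = 0.25),
               "merge")
})

test_that("reference beat stream is a pure time shift with identical intervals", {
  cfg <- modulation_config(
    modulation_phase(100, 75, lf_amp = 0.03, hf_amp = 0.03), seed = 4)
  ppg <- simulate_beat_series(cfg)
  ecg <- derive_reference_beats(ppg, transit_delay_s = 0.3)
  expect_equal(ppg$beat_time_s - ecg$beat_time_s,
               rep(0.3, nrow(ppg)), tolerance = 1e-12)
  expect_identical(derive_reference_beats(ppg, 0)$beat_time_s,
                   ppg$beat_time_s)
  expect_equal(beats_to_intervals(ppg)$pp_ms, beats_to_intervals(ecg)$pp_ms,
               tolerance = 1e-12)
  expect_error(derive_reference_beats(ppg, -0.1), ">= 0")
})

test_that("cohort simulator honors configured moments, seeds and truncation", {
  ord <- canonical_features()
  # degenerate draw: zero SDs reproduce the mean vector exactly
  mu <- setNames(c(85, 88, 82, 56, 29, 63, 3.5, 6.6, 4.6), ord)
  gp0 <- group_params(mu, setNames(rep(0, 9), ord),
                      mu + 1, setNames(rep(0, 9), ord))
  coh0 <- simulate_feature_cohort(gp0, 3, 0, seed = 5)
  for (v in ord) expect_equal(coh0[[v]], rep(mu[[v]], 3))

  # determinism
  gp <- reference_group_params(healthy_lfhf_after_mean = 1.5)
  expect_identical(simulate_feature_cohort(gp, 6, 14, seed = 11),
                   simulate_feature_cohort(gp, 6, 14, seed = 11))

  # moment convergence at n = 5000 on an untruncated cell (3-sigma band)
  big <- simulate_feature_cohort(gp, 5000, 0, seed = 12)
  se <- 8.4 / sqrt(5000)
  expect_lt(abs(mean(big$hr_before) - 84.7), 3 * se)
  expect_lt(abs(sd(big$hr_before) - 8.4), 3 * se)
  # truncated cells stay strictly positive despite SD > mean
  bigh <- simulate_feature_cohort(gp, 0, 2000, seed = 13)
  expect_true(all(bigh$hf_before > 0) && all(bigh$lfhf_after > 0))
})

test_that("reference group parameters demand the unavailable cell explicitly", {
  expect_error(reference_group_params(), "lfhf_after")
  gp <- reference_group_params(healthy_lfhf_after_mean = 1.5)
  expect_equal(gp$mdd$mean[["hr_before"]], 84.7)
  expect_equal(gp$healthy$sd[["lfhf_after"]], 1)
  # a missing cell in hand-built params is named in the error
  mu <- gp$mdd$mean
  mu[["hf_during"]] <- NA_real_
  expect_error(group_params(mu, gp$mdd$sd, gp$healthy$mean, gp$healthy$sd),
               "hf_during")
})
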