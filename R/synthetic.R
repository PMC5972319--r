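#' Describe one recording phase of an autonomic modulation schedule
#'
#' Helper building a single row of the phase table consumed by
#' [modulation_config()]. Each phase has its own mean heart rate and its own
#' low-frequency (LF) and high-frequency (HF) sinusoidal modulation of the
#' instantaneous beat rate, so that task-locked autonomic transients (the
#' before / during / after structure of a mental-task protocol) can be
#' emulated with controlled band powers.
#'
#' @param duration_s Phase length in seconds (> 0).
#' @param mean_hr Mean heart rate in beats per minute, in (30, 200).
#' @param lf_amp,hf_amp Dimensionless modulation amplitudes (>= 0, < 1;
#'   their sum must stay below 1 so the instantaneous rate stays positive).
#' @param lf_freq LF modulation frequency in Hz, in (0.04, 0.15].
#' @param hf_freq HF modulation frequency in Hz, in (0.15, 0.4].
#' @return A one-row tibble.
#' @export
modulation_phase <- function(duration_s, mean_hr, lf_amp = 0, hf_amp = 0,
                             lf_freq = 0.1, hf_freq = 0.25) {
  tibble(duration_s = duration_s, mean_hr = mean_hr,
         lf_amp = lf_amp, hf_amp = hf_amp,
         lf_freq = lf_freq, hf_freq = hf_freq)
}

#' Build and validate a beat-rate modulation configuration
#'
#' The configuration drives the integral-pulse-frequency-modulation (IPFM)
#' beat simulator [simulate_beat_series()]. The instantaneous rate is
#' `(1 + m(t)) / T0(t)` where `T0` is the phase's mean beat period and
#' `m(t)` is the sum of one LF and one HF sinusoid with phase-specific
#' amplitudes. Sinusoid initial phases are drawn uniformly on `[0, 2*pi)`
#' from `seed` unless fixed explicitly.
#'
#' @param phases A data frame of phases as built by [modulation_phase()]
#'   (rows are concatenated in time).
#' @param seed Integer seed for the random initial phases (optional).
#' @param lf_phase,hf_phase Fixed initial phases in radians (optional;
#'   override the seeded draw).
#' @return An object of class `modulation_config`.
#' @export
modulation_config <- function(phases, seed = NULL,
                              lf_phase = NULL, hf_phase = NULL) {
  phases <- as_tibble(phases)
  required <- c("duration_s", "mean_hr", "lf_amp", "hf_amp",
                "lf_freq", "hf_freq")
  missing <- setdiff(required, names(phases))
  if (length(missing)) {
    abort(paste0("`phases` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(phases) < 1L) abort("`phases` needs at least one row.")
  with(phases, {
    if (any(duration_s <= 0)) abort("phase durations must be > 0")
    if (any(mean_hr <= 30 | mean_hr >= 200)) {
      abort("mean_hr must lie in (30, 200) bpm")
    }
    if (any(lf_freq <= 0.04 | lf_freq > 0.15)) {
      abort("lf_freq must lie in (0.04, 0.15] Hz")
    }
    if (any(hf_freq <= 0.15 | hf_freq > 0.4)) {
      abort("hf_freq must lie in (0.15, 0.4] Hz")
    }
    if (any(lf_amp < 0 | hf_amp < 0 | lf_amp >= 1 | hf_amp >= 1)) {
      abort("modulation amplitudes must be >= 0 and < 1")
    }
    if (any(lf_amp + hf_amp >= 1)) {
      abort(paste("lf_amp + hf_amp must be < 1 in every phase:",
                  "the instantaneous beat rate could become non-positive"))
    }
  })
  structure(list(phases = phases, seed = seed,
                 lf_phase = lf_phase, hf_phase = hf_phase),
            class = "modulation_config")
}

#' Translate target phase-average HRV features into a modulation schedule
#'
#' Inverts the small-modulation IPFM relationships `HF ~ (hf_amp * T0_ms)^2 / 2`
#' and `LF = LF/HF * HF` to pick per-phase sinusoid amplitudes whose realized
#' windowed band powers approximate the requested values, so a synthetic
#' subject can be simulated from group-level summary statistics (mean HR in
#' bpm, HF power in ms^2, LF/HF ratio per phase).
#'
#' @param hr,hf_ms2,lfhf Numeric vectors, one value per phase.
#' @param durations_s Phase durations in seconds (default the 320-s
#'   three-phase protocol: 100 s rest, 100 s mental task, 120 s rest).
#' @param lf_freq,hf_freq Modulation frequencies in Hz.
#' @inheritParams modulation_config
#' @return A `modulation_config`.
#' @export
modulation_from_features <- function(hr, hf_ms2, lfhf,
                                     durations_s = c(100, 100, 120),
                                     lf_freq = 0.1, hf_freq = 0.25,
                                     seed = NULL,
                                     lf_phase = NULL, hf_phase = NULL) {
  if (length(hr) != length(durations_s) || length(hf_ms2) != length(hr) ||
      length(lfhf) != length(hr)) {
    abort("hr, hf_ms2, lfhf and durations_s must have one value per phase.")
  }
  t0_ms <- 60000 / hr
  hf_amp <- sqrt(2 * hf_ms2) / t0_ms
  lf_amp <- sqrt(2 * hf_ms2 * lfhf) / t0_ms
  phases <- tibble(duration_s = durations_s, mean_hr = hr,
                   lf_amp = lf_amp, hf_amp = hf_amp,
                   lf_freq = lf_freq, hf_freq = hf_freq)
  modulation_config(phases, seed = seed,
                    lf_phase = lf_phase, hf_phase = hf_phase)
}

#' Simulate a beat series by integral pulse frequency modulation
#'
#' Beat `k` fires when the running integral of the instantaneous rate
#' `(1 + m(t)) / T0(t)` reaches `k`. With all modulation amplitudes zero the
#' construction degenerates to a metronome: beats at exactly `k * 60/mean_hr`
#' seconds. LF/HF amplitudes translate monotonically into realized tachogram
#' band powers, which is what makes the generator useful as ground truth for
#' the spectral stages.
#'
#' @param config A [modulation_config()].
#' @param dt_s Integration grid step in seconds (default 1 ms).
#' @return A tibble with column `beat_time_s`, strictly increasing.
#' @export
simulate_beat_series <- function(config, dt_s = 0.001) {
  if (!inherits(config, "modulation_config")) {
    abort("`config` must be a modulation_config")
  }
  ph <- config$phases
  total <- sum(ph$duration_s)
  phi <- with_seed(config$seed, runif(2, 0, 2 * pi))
  phi_lf <- if (is.null(config$lf_phase)) phi[1] else config$lf_phase
  phi_hf <- if (is.null(config$hf_phase)) phi[2] else config$hf_phase

  tt <- seq(0, total, by = dt_s)
  bounds <- cumsum(ph$duration_s)
  idx <- findInterval(tt, c(0, head(bounds, -1)), rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(ph)] <- nrow(ph)
  t0 <- 60 / ph$mean_hr[idx]
  m <- ph$lf_amp[idx] * sin(2 * pi * ph$lf_freq[idx] * tt + phi_lf) +
    ph$hf_amp[idx] * sin(2 * pi * ph$hf_freq[idx] * tt + phi_hf)
  rate <- (1 + m) / t0
  # trapezoidal cumulative integral of the rate; exact for constant rate
  integral <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt_s))
  n_beats <- floor(integral[length(integral)])
  if (n_beats < 1L) abort("recording too short: no beat fires")
  beats <- approx(integral, tt, xout = seq_len(n_beats), ties = "ordered")$y
  tibble(beat_time_s = beats)
}

# Asymmetric raised-cosine pulse template: fast rise, slow decay, peak at 0.
pulse_template_value <- function(u, rise_s, decay_s) {
  out <- numeric(length(u))
  r <- u >= -rise_s & u < 0
  d <- u >= 0 & u <= decay_s
  out[r] <- 0.5 * (1 - cos(pi * (u[r] + rise_s) / rise_s))
  out[d] <- 0.5 * (1 + cos(pi * u[d] / decay_s))
  out
}

#' Render a synthetic fingertip pulse waveform from beat times
#'
#' Superposes an asymmetric raised-cosine pulse (fast systolic rise, slower
#' decay, peak aligned with the beat time) at every beat, optionally adds a
#' sinusoidal baseline drift and white Gaussian noise at a configured SNR,
#' and quantizes the result to an ADC-like grid, emulating a 100-Hz, 12-bit
#' acquisition chain.
#'
#' @param beats Tibble with `beat_time_s` (or a numeric vector of beat times).
#' @param sampling_rate_hz Sampling rate in Hz (default 100).
#' @param quantization_bits ADC resolution in bits, in \[8, 16\] (default 12).
#' @param rise_s,decay_s Pulse template rise and decay times in seconds
#'   (total width defaults to 0.35 s).
#' @param amplitude Peak pulse amplitude in arbitrary ADC units.
#' @param noise_snr_db Signal-to-noise ratio in dB (`Inf` disables noise).
#' @param drift_amp Baseline drift amplitude (same units as `amplitude`).
#' @param drift_freq_hz Baseline drift frequency in Hz.
#' @param duration_s Recording length in seconds (default: covers all beats).
#' @param seed Seed for the noise draw.
#' @return A tibble of class `ppg_waveform` with columns `time_s`,
#'   `amplitude`, and attribute `fs_hz`.
#' @export
render_ppg_waveform <- function(beats, sampling_rate_hz = 100,
                                quantization_bits = 12,
                                rise_s = 0.10, decay_s = 0.25,
                                amplitude = 1000,
                                noise_snr_db = Inf,
                                drift_amp = 0, drift_freq_hz = 0.05,
                                duration_s = NULL, seed = NULL) {
  bt <- beat_times(beats)
  if (length(bt) < 1L) abort("`beats` must contain at least one beat")
  if (quantization_bits < 8 || quantization_bits > 16) {
    abort("quantization_bits must lie in [8, 16]")
  }
  width <- rise_s + decay_s
  if (sampling_rate_hz <= 2 / width) {
    abort("sampling_rate_hz too low for the pulse template width")
  }
  if (length(bt) > 1L && width >= min(diff(bt))) {
    abort(paste("pulse template is wider than the shortest inter-beat",
                "interval: pulses would merge ambiguously"))
  }
  if (is.null(duration_s)) duration_s <- max(bt) + decay_s
  n <- floor(duration_s * sampling_rate_hz) + 1L
  tt <- (seq_len(n) - 1L) / sampling_rate_hz
  signal <- numeric(n)
  for (b in bt) {
    i0 <- max(1L, ceiling((b - rise_s) * sampling_rate_hz) + 1L)
    i1 <- min(n, floor((b + decay_s) * sampling_rate_hz) + 1L)
    if (i0 > i1) next
    sel <- i0:i1
    signal[sel] <- signal[sel] +
      amplitude * pulse_template_value(tt[sel] - b, rise_s, decay_s)
  }
  x <- signal + drift_amp * sin(2 * pi * drift_freq_hz * tt)
  if (is.finite(noise_snr_db)) {
    noise_sd <- sqrt(var(signal) / 10^(noise_snr_db / 10))
    x <- x + with_seed(seed, rnorm(n, 0, noise_sd))
  }
  # uniform quantization over the observed range to 2^bits levels
  lo <- min(x)
  lsb <- (max(x) - lo) / (2^quantization_bits - 1)
  if (lsb > 0) x <- lo + round((x - lo) / lsb) * lsb
  new_ppg_waveform(tibble(time_s = tt, amplitude = x), sampling_rate_hz)
}

new_ppg_waveform <- function(df, fs_hz) {
  out <- as_tibble(df)
  attr(out, "fs_hz") <- fs_hz
  class(out) <- c("ppg_waveform", class(out))
  out
}

beat_times <- function(beats) {
  bt <- if (is.data.frame(beats)) {
    if (!"beat_time_s" %in% names(beats)) {
      abort("`beats` must have a `beat_time_s` column")
    }
    beats$beat_time_s
  } else {
    as.numeric(beats)
  }
  if (length(bt) > 1L && any(diff(bt) <= 0)) {
    abort("beat times must be strictly increasing")
  }
  bt
}

#' Derive the reference (ECG-like) beat stream from pulse beats
#'
#' The fingertip pulse wave peaks a pulse-transit delay after the
#' electrocardiographic R wave (around 300 ms). Shifting all pulse-peak
#' times back by that delay yields the R-peak stream an ECG reference would
#' record; the two streams share identical interbeat intervals, which is the
#' structural basis of the PPG-vs-ECG agreement analysis.
#'
#' @param beats Tibble with `beat_time_s`.
#' @param transit_delay_s Pulse transit delay in seconds (>= 0, default 0.3).
#' @return A tibble with `beat_time_s`, shifted earlier by the delay.
#' @export
derive_reference_beats <- function(beats, transit_delay_s = 0.3) {
  stop_not_scalar_number(transit_delay_s, "transit_delay_s")
  if (transit_delay_s < 0) abort("transit_delay_s must be >= 0")
  tibble(beat_time_s = beat_times(beats) - transit_delay_s)
}

#' Per-group feature distribution parameters for the cohort simulator
#'
#' Bundles per-group means and standard deviations for the nine screening
#' features (HR, HF, LF/HF in each of the before / during / after phases),
#' with an optional common 9x9 correlation matrix. HF and LF/HF draws are
#' truncated to be positive (resample-until-positive), since published SDs
#' can exceed means for those variables.
#'
#' @param mdd_mean,mdd_sd,healthy_mean,healthy_sd Named numeric vectors over
#'   the canonical feature order (see [canonical_features()]).
#' @param correlation Optional 9x9 symmetric positive semi-definite
#'   correlation matrix shared by both groups.
#' @return An object of class `group_params`.
#' @export
group_params <- function(mdd_mean, mdd_sd, healthy_mean, healthy_sd,
                         correlation = NULL) {
  ord <- canonical_feature_order()
  chk <- function(x, name, sd = FALSE) {
    if (is.null(names(x))) names(x) <- ord
    missing <- setdiff(ord, names(x))
    if (length(missing)) {
      abort(sprintf("`%s` is missing value(s) for: %s", name,
                    paste(missing, collapse = ", ")))
    }
    x <- x[ord]
    bad <- !is.finite(x)
    if (any(bad)) {
      abort(sprintf("`%s` has a missing or non-finite value for cell(s): %s",
                    name, paste(ord[bad], collapse = ", ")))
    }
    if (sd && any(x < 0)) abort(sprintf("`%s` must be >= 0", name))
    x
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(correlation, t(correlation))) ||
        nrow(correlation) != 9L) {
      abort("`correlation` must be a symmetric 9x9 matrix")
    }
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) abort("`correlation` must be positive semi-definite")
  }
  structure(list(mdd = list(mean = chk(mdd_mean, "mdd_mean"),
                            sd = chk(mdd_sd, "mdd_sd", sd = TRUE)),
                 healthy = list(mean = chk(healthy_mean, "healthy_mean"),
                                sd = chk(healthy_sd, "healthy_sd", sd = TRUE)),
                 correlation = correlation),
            class = "group_params")
}

#' Canonical screening feature names
#'
#' Measure-major order: HR, then HF, then LF/HF, each before / during /
#' after the mental task. All feature tables, models and cohort files in the
#' package use exactly this column order.
#'
#' @return Character vector of the nine feature names.
#' @export
canonical_features <- function() canonical_feature_order()

#' Reference clinical group parameters (published summary statistics)
#'
#' Group means and SDs of the nine screening variables for the depressed
#' (MDD) and healthy groups of the clinical study the frozen screening model
#' was trained on. The healthy after-task LF/HF mean is not legible in the
#' published table (only its SD, 1, is printed), so that one value must be
#' supplied explicitly; no default is invented.
#'
#' @param healthy_lfhf_after_mean Mean healthy LF/HF after the mental task
#'   (required; the published value is unavailable).
#' @param correlation Optional 9x9 correlation matrix, see [group_params()].
#' @return A [group_params()] object.
#' @export
reference_group_params <- function(healthy_lfhf_after_mean,
                                   correlation = NULL) {
  if (missing(healthy_lfhf_after_mean)) {
    abort(paste("`healthy_lfhf_after_mean` must be supplied: the published",
                "healthy after-task LF/HF mean is unavailable (cell",
                "lfhf_after, healthy group)"))
  }
  stop_not_scalar_number(healthy_lfhf_after_mean, "healthy_lfhf_after_mean")
  ord <- canonical_feature_order()
  group_params(
    mdd_mean = setNames(c(84.7, 87.9, 82.2, 56.4, 29.4, 62.8,
                          3.5, 6.6, 4.6), ord),
    mdd_sd = setNames(c(8.4, 8, 8.3, 54.4, 21.3, 31.8,
                        1.3, 2.8, 2.76), ord),
    healthy_mean = setNames(c(73.8, 77.8, 70, 365.9, 109.9, 334.4,
                              1.3, 5, healthy_lfhf_after_mean), ord),
    healthy_sd = setNames(c(8.5, 8.5, 8.3, 519.4, 170.8, 370.1,
                            2.5, 5.4, 1), ord),
    correlation = correlation
  )
}

# Truncated positive features: HF and LF/HF cells must be > 0.
positive_features <- function() {
  c("hf_before", "hf_during", "hf_after",
    "lfhf_before", "lfhf_during", "lfhf_after")
}

draw_group <- function(g, n, correlation, label) {
  ord <- canonical_feature_order()
  pos <- ord %in% positive_features()
  if (n == 0L) {
    out <- as_tibble(setNames(rep(list(numeric(0)), 9), ord))
    return(out)
  }
  if (is.null(correlation)) {
    # independent cells: exact truncated normal by per-cell resampling
    cols <- lapply(seq_along(ord), function(j) {
      x <- rnorm(n, g$mean[j], g$sd[j])
      if (pos[j]) {
        for (it in seq_len(10000)) {
          bad <- which(x <= 0)
          if (!length(bad)) break
          x[bad] <- rnorm(length(bad), g$mean[j], g$sd[j])
        }
        if (any(x <= 0)) abort("could not draw positive values; check params")
      }
      x
    })
    return(as_tibble(setNames(cols, ord)))
  }
  L <- chol(correlation + diag(1e-10, 9))
  draw_rows <- function(k) {
    z <- matrix(rnorm(k * 9), k, 9) %*% L
    sweep(sweep(z, 2, g$sd, `*`), 2, g$mean, `+`)
  }
  x <- draw_rows(n)
  for (it in seq_len(10000)) {
    bad <- which(apply(x[, pos, drop = FALSE] <= 0, 1, any))
    if (!length(bad)) break
    x[bad, ] <- draw_rows(length(bad))
  }
  if (any(x[, pos] <= 0)) abort("could not draw positive values; check params")
  colnames(x) <- ord
  as_tibble(x)
}

#' Simulate a labeled feature cohort from group parameters
#'
#' Draws subjects from (optionally correlated) Gaussians with the configured
#' per-group means and SDs; HF and LF/HF cells are resampled until positive.
#' Reproducible under a fixed seed.
#'
#' @param params A [group_params()] object.
#' @param n_mdd,n_healthy Number of subjects per group (>= 0).
#' @param seed Integer seed.
#' @return A tibble with `subject_id`, `label` (`"MDD"` / `"healthy"`), and
#'   the nine canonical feature columns.
#' @export
simulate_feature_cohort <- function(params, n_mdd, n_healthy, seed = NULL) {
  if (!inherits(params, "group_params")) {
    abort("`params` must be a group_params object")
  }
  if (n_mdd < 0 || n_healthy < 0) abort("group sizes must be >= 0")
  with_seed(seed, {
    mdd <- draw_group(params$mdd, n_mdd, params$correlation, "MDD")
    hea <- draw_group(params$healthy, n_healthy, params$correlation, "healthy")
    out <- bind_rows(
      dplyr::bind_cols(tibble(subject_id = sprintf("mdd_%03d", seq_len(n_mdd)),
                              label = rep("MDD", n_mdd)), mdd),
      dplyr::bind_cols(tibble(subject_id = sprintf("hv_%03d", seq_len(n_healthy)),
                              label = rep("healthy", n_healthy)), hea)
    )
    out
  })
}
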