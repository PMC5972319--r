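# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, half_width) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i0 <- pmax(1L, seq_len(n) - half_width)
  i1 <- pmin(n, seq_len(n) + half_width)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

# Rolling quantile evaluated on a coarse 1-s grid and interpolated back,
# keeping the adaptive threshold cheap on long recordings.
rolling_quantile <- function(x, fs, window_s, prob) {
  n <- length(x)
  centers <- unique(pmin(n, seq(1L, n, by = max(1L, round(fs)))))
  half <- round(window_s * fs / 2)
  q <- vapply(centers, function(c0) {
    seg <- x[max(1L, c0 - half):min(n, c0 + half)]
    quantile(seg, prob, names = FALSE)
  }, numeric(1))
  if (length(centers) == 1L) return(rep(q, n))
  approx(centers, q, xout = seq_len(n), rule = 2)$y
}

#' Detect pulse peaks in a raw pulse waveform
#'
#' Conventional dependency-light systolic-peak detector: a 1-s moving-average
#' detrend, a short low-pass smoothing of the candidate trace, an adaptive
#' threshold at a rolling amplitude percentile, local maxima above threshold,
#' a physiological refractory period (default 300 ms, a 200-bpm ceiling),
#' and parabolic interpolation around each sample argmax for sub-sample peak
#' times. By default a second, adaptive template pass then re-aligns every
#' beat by cross-correlation with the ensemble-averaged pulse: the
#' autocorrelation of any pulse shape is symmetric about zero lag, so this
#' alignment is free of the systematic late bias that apex interpolation
#' suffers on pulses with a slow, noise-prone decay. The detector is
#' invariant to gain and constant offset of the waveform.
#'
#' @param waveform A tibble with `time_s` and `amplitude`
#'   (e.g. from [render_ppg_waveform()] or [read_waveform_csv()]).
#' @param detrend_window_s Moving-average detrend window in seconds.
#' @param smooth_window_s Low-pass moving-average window for candidate
#'   finding, in seconds.
#' @param threshold_window_s Window of the rolling percentile threshold.
#' @param threshold_quantile Amplitude percentile for the threshold.
#' @param refractory_s Minimum spacing between accepted peaks in seconds.
#' @param template_refine Run the adaptive template re-alignment pass
#'   (default `TRUE`).
#' @return A tibble with `beat_time_s` (strictly increasing). A flat signal
#'   yields zero rows with a warning.
#' @export
detect_pulse_peaks <- function(waveform,
                               detrend_window_s = 1,
                               smooth_window_s = 0.05,
                               threshold_window_s = 10,
                               threshold_quantile = 0.8,
                               refractory_s = 0.3,
                               template_refine = TRUE) {
  if (!is.data.frame(waveform) ||
      !all(c("time_s", "amplitude") %in% names(waveform))) {
    abort("`waveform` must have columns time_s and amplitude")
  }
  tt <- waveform$time_s
  x <- waveform$amplitude
  n <- length(x)
  if (n < 2L) abort("waveform needs at least 2 samples")
  fs <- attr(waveform, "fs_hz")
  if (is.null(fs)) fs <- 1 / median(diff(tt))
  if (fs < 25) abort("sampling rate below 25 Hz: too low for peak detection")
  if ((tt[n] - tt[1]) < 10) {
    abort("waveform shorter than 10 s: too short for meaningful detection")
  }
  if (max(x) == min(x)) {
    warn("flat waveform: no pulses detected")
    return(tibble(beat_time_s = numeric(0)))
  }
  d <- x - moving_average(x, round(detrend_window_s * fs / 2))
  sm <- moving_average(d, max(1L, round(smooth_window_s * fs / 2)))
  thr <- rolling_quantile(sm, fs, threshold_window_s, threshold_quantile)
  mid <- 2:(n - 1L)
  cand <- mid[sm[mid] >= sm[mid - 1L] & sm[mid] > sm[mid + 1L] &
                sm[mid] > thr[mid]]
  if (!length(cand)) {
    warn("no peaks above the adaptive threshold")
    return(tibble(beat_time_s = numeric(0)))
  }
  # greedy refractory: accept candidates from strongest down, rejecting any
  # within refractory_s of an already accepted peak
  cand <- cand[order(sm[cand], decreasing = TRUE)]
  accepted <- integer(0)
  accepted_t <- numeric(0)
  for (i in cand) {
    ti <- tt[i]
    if (!length(accepted_t) || min(abs(accepted_t - ti)) >= refractory_s) {
      accepted <- c(accepted, i)
      accepted_t <- c(accepted_t, ti)
    }
  }
  accepted <- sort(accepted)
  out <- if (template_refine && length(accepted) >= 5L) {
    template_realign(d, tt, accepted, fs)
  } else {
    # parabolic sub-sample refinement on the smoothed detrended signal
    vapply(accepted, function(i) {
      if (i <= 1L || i >= n) return(tt[i])
      denom <- sm[i - 1L] - 2 * sm[i] + sm[i + 1L]
      if (denom >= 0) return(tt[i])
      delta <- 0.5 * (sm[i - 1L] - sm[i + 1L]) / denom
      delta <- max(-0.5, min(0.5, delta))
      tt[i] + delta / fs
    }, numeric(1))
  }
  out <- sort(out)
  # final refractory guard after sub-sample refinement
  keep <- c(TRUE, diff(out) >= refractory_s)
  tibble(beat_time_s = out[keep])
}

# Re-align detected beats against the ensemble-averaged pulse. The mean
# pulse over all beats is nearly noise-free; its apex (located on a dense
# spline grid) fixes the absolute peak position, and per-beat offsets come
# from the cross-correlation maximum, which is unbiased for any pulse shape.
template_realign <- function(d, tt, centers, fs,
                             half_width_s = 0.35, max_lag = 5L) {
  n <- length(d)
  W <- max(5L, round(half_width_s * fs))
  ok <- centers > (W + max_lag) & centers <= (n - W - max_lag)
  if (sum(ok) < 5L) return(tt[centers])
  u <- (-W):W
  tmpl <- rowMeans(vapply(centers[ok], function(c0) d[c0 + u],
                          numeric(length(u))))
  sf <- splinefun(u, tmpl, method = "natural")
  uf <- seq(-max_lag - 1, max_lag + 1, by = 0.01)
  apex_u <- uf[which.max(sf(uf))]
  lags <- (-max_lag):max_lag
  vapply(centers, function(c0) {
    if (c0 <= W + max_lag || c0 > n - W - max_lag) return(tt[c0])
    cc <- vapply(lags, function(l) sum(tmpl * d[c0 + u + l]), numeric(1))
    j <- which.max(cc)
    delta <- 0
    if (j > 1L && j < length(lags)) {
      denom <- cc[j - 1L] - 2 * cc[j] + cc[j + 1L]
      if (denom < 0) {
        delta <- max(-0.5, min(0.5, 0.5 * (cc[j - 1L] - cc[j + 1L]) / denom))
      }
    }
    tt[c0] + (lags[j] + delta + apex_u) / fs
  }, numeric(1))
}

#' Convert beat times to a peak-to-peak interval series
#'
#' @param beats Tibble with `beat_time_s` (>= 2 beats, strictly increasing).
#' @return A tibble with `anchor_time_s` (time of the later beat of each
#'   pair), `pp_ms` (interval length in milliseconds) and `flag`
#'   (artifact marker, all `FALSE` here).
#' @export
beats_to_intervals <- function(beats) {
  bt <- beat_times(beats)
  if (length(bt) < 2L) abort("need at least 2 beats to form intervals")
  tibble(anchor_time_s = bt[-1],
         pp_ms = diff(bt) * 1000,
         flag = FALSE)
}

check_intervals <- function(intervals) {
  if (!is.data.frame(intervals) ||
      !all(c("anchor_time_s", "pp_ms") %in% names(intervals))) {
    abort("`intervals` must have columns anchor_time_s and pp_ms")
  }
  if (any(intervals$pp_ms <= 0)) abort("pp_ms must be > 0")
  if (nrow(intervals) > 1L && any(diff(intervals$anchor_time_s) <= 0)) {
    abort("anchor times must be strictly increasing")
  }
  invisible(intervals)
}

#' Flag and repair artifactual peak-to-peak intervals
#'
#' Intervals outside a physiological gate (default \[300, 2000\] ms) or
#' deviating more than `max_deviation` from the running 5-point median of
#' their neighbourhood are flagged and replaced by linear interpolation over
#' the surrounding clean intervals. Small interval artifacts matter because
#' they bleed into the frequency-domain indices (HF, LF/HF) downstream. If
#' more than `max_flagged_frac` of intervals are flagged the recording is
#' rejected as too poor to repair.
#'
#' @param intervals An interval tibble from [beats_to_intervals()]
#'   (>= 5 intervals).
#' @param min_ms,max_ms Physiological interval gate in milliseconds.
#' @param max_deviation Maximal relative deviation from the running median.
#' @param max_flagged_frac Rejection threshold on the flagged fraction.
#' @return The interval tibble with the same number of rows, repaired values
#'   and updated `flag` column.
#' @export
clean_intervals <- function(intervals, min_ms = 300, max_ms = 2000,
                            max_deviation = 0.25, max_flagged_frac = 0.2) {
  check_intervals(intervals)
  pp <- intervals$pp_ms
  n <- length(pp)
  if (n < 5L) abort("need at least 5 intervals for artifact screening")
  med <- stats::runmed(pp, 5, endrule = "median")
  flag <- pp < min_ms | pp > max_ms | abs(pp - med) / med > max_deviation
  frac <- mean(flag)
  if (frac > max_flagged_frac) {
    abort(sprintf(paste("recording rejected: %.0f%% of intervals flagged as",
                        "artifacts (limit %.0f%%); quality too poor"),
                  100 * frac, 100 * max_flagged_frac))
  }
  out <- intervals
  out$flag <- flag
  if (any(flag)) {
    good <- which(!flag)
    out$pp_ms[flag] <- approx(intervals$anchor_time_s[good], pp[good],
                              xout = intervals$anchor_time_s[flag],
                              rule = 2)$y
  }
  out
}
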