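# Frequency-band conventions. Half-open bands (lo, hi] so the shared 0.15-Hz
# edge is never counted twice.
LF_BAND <- c(0.04, 0.15)
HF_BAND <- c(0.15, 0.40)
TACHOGRAM_FS <- 4      # Hz
SPECTRAL_WINDOW_S <- 30
SPECTRAL_STEP_S <- 2

#' Resample an interval series onto a uniform 4-Hz tachogram
#'
#' Peak-to-peak intervals are irregular samples of the underlying interval
#' process; Fourier analysis needs an equally spaced series. A natural cubic
#' spline through (anchor time, interval) is evaluated on a uniform 0.25-s
#' grid. By default the grid spans the anchor range; explicit `start_s` /
#' `end_s` allow aligning the grid with the recording extent (values beyond
#' the anchors come from the spline's natural linear extrapolation).
#'
#' @param intervals Interval tibble (>= 4 intervals spanning >= 1 s).
#' @param start_s,end_s Optional grid extent in seconds.
#' @return A tibble of class `tachogram` with `grid_time_s` and `pp_ms`.
#' @export
resample_tachogram <- function(intervals, start_s = NULL, end_s = NULL) {
  check_intervals(intervals)
  at <- intervals$anchor_time_s
  if (anyDuplicated(at)) abort("duplicate anchor times")
  if (nrow(intervals) < 4L) abort("need at least 4 intervals to interpolate")
  if (diff(range(at)) < 1) abort("intervals must span at least 1 s")
  if (is.null(start_s)) start_s <- at[1]
  if (is.null(end_s)) end_s <- at[length(at)]
  sf <- splinefun(at, intervals$pp_ms, method = "natural")
  grid <- seq(start_s, end_s, by = 1 / TACHOGRAM_FS)
  out <- tibble(grid_time_s = grid, pp_ms = sf(grid))
  class(out) <- c("tachogram", class(out))
  out
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n)

band_bins <- function(n, fs, band) {
  f <- (seq_len(n %/% 2)) * fs / n     # positive-frequency bins, excl. DC
  which(f > band[1] & f <= band[2] + 1e-12)
}

#' LF and HF band powers of one 30-s tachogram segment
#'
#' Removes the segment mean, applies a Hann window, takes the 120-point
#' discrete Fourier transform and sums per-bin one-sided powers over the LF
#' band (0.04, 0.15\] Hz and the HF band (0.15, 0.4\] Hz. Powers are
#' normalized by the window's power loss so that a pure in-band sinusoid of
#' amplitude `A` ms contributes band power `A^2/2` ms^2, making the window
#' choice testable and swappable.
#'
#' @param segment Numeric vector of exactly 120 tachogram samples (30 s at
#'   4 Hz), in ms. No silent padding is performed.
#' @return A one-row tibble with `lf_ms2` and `hf_ms2`.
#' @export
band_powers <- function(segment) {
  n_expect <- SPECTRAL_WINDOW_S * TACHOGRAM_FS
  if (!is.numeric(segment) || length(segment) != n_expect) {
    abort(sprintf("`segment` must contain exactly %d samples (got %d)",
                  n_expect, length(segment)))
  }
  n <- length(segment)
  w <- hann_window(n)
  xw <- (segment - mean(segment)) * w
  X <- fft(xw)
  # one-sided per-bin power with energy normalization: an exact-bin sinusoid
  # of amplitude A sums to A^2/2 across its leakage bins
  p <- 2 * Mod(X[seq_len(n %/% 2) + 1L])^2 / (n * sum(w^2))
  tibble(lf_ms2 = sum(p[band_bins(n, TACHOGRAM_FS, LF_BAND)]),
         hf_ms2 = sum(p[band_bins(n, TACHOGRAM_FS, HF_BAND)]))
}

#' Mean heart rate of the intervals anchored inside a window
#'
#' `60000 / mean(pp_ms)` over intervals whose anchor time falls in
#' `[start_s, end_s)`. An empty window yields `NA` (propagated, never zero).
#'
#' @param intervals Interval tibble.
#' @param start_s,end_s Window bounds in seconds.
#' @return Heart rate in bpm, or `NA_real_` for an empty window.
#' @export
window_heart_rate <- function(intervals, start_s, end_s) {
  check_intervals(intervals)
  sel <- intervals$anchor_time_s >= start_s & intervals$anchor_time_s < end_s
  if (!any(sel)) return(NA_real_)
  60000 / mean(intervals$pp_ms[sel])
}

#' Time-resolved HRV series from sliding spectral windows
#'
#' Advances a 30-s analysis window in 2-s steps over the uniform tachogram;
#' each window emits LF/HF band powers ([band_powers()]) plus the window's
#' mean heart rate ([window_heart_rate()]), time-stamped at the window
#' center. The first center lies 15 s after the grid start.
#'
#' @param tachogram A [resample_tachogram()] result.
#' @param intervals The interval tibble the tachogram was built from (used
#'   for the heart-rate estimate).
#' @return A tibble of class `hrv_series` with `window_center_s`, `hr_bpm`,
#'   `lf_ms2`, `hf_ms2`, `lfhf`.
#' @export
sliding_hrv <- function(tachogram, intervals) {
  if (!is.data.frame(tachogram) ||
      !all(c("grid_time_s", "pp_ms") %in% names(tachogram))) {
    abort("`tachogram` must have columns grid_time_s and pp_ms")
  }
  check_intervals(intervals)
  n_win <- SPECTRAL_WINDOW_S * TACHOGRAM_FS
  step <- SPECTRAL_STEP_S * TACHOGRAM_FS
  n <- nrow(tachogram)
  if (n < n_win) {
    abort(sprintf("recording shorter than the %d-s spectral window",
                  SPECTRAL_WINDOW_S))
  }
  starts <- seq(1L, n - n_win + 1L, by = step)
  rows <- lapply(starts, function(j) {
    seg <- tachogram$pp_ms[j:(j + n_win - 1L)]
    t0 <- tachogram$grid_time_s[j]
    bp <- band_powers(seg)
    hr <- window_heart_rate(intervals, t0, t0 + SPECTRAL_WINDOW_S)
    tibble(window_center_s = t0 + SPECTRAL_WINDOW_S / 2,
           hr_bpm = hr, lf_ms2 = bp$lf_ms2, hf_ms2 = bp$hf_ms2,
           lfhf = ifelse(bp$hf_ms2 > 0, bp$lf_ms2 / bp$hf_ms2, NA_real_))
  })
  out <- bind_rows(rows)
  class(out) <- c("hrv_series", class(out))
  out
}
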