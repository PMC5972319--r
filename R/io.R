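# Plain-text exchange formats: CSV for series, JSON for models and results.
# Numbers are written with full double precision so write-then-read
# round-trips values to better than 1e-12.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.15g", v)
  }, character(1))
  out
}

write_plain_csv <- function(df, path, header_lines = character(0)) {
  cols <- names(df)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  }), sep = ","))
  writeLines(c(header_lines, paste(cols, collapse = ","), body), path)
}

parse_csv_file <- function(path, skip = 0L) {
  df <- tryCatch(
    read.csv(path, skip = skip, stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("malformed CSV '%s': %s", path,
                                      conditionMessage(e))))
  as_tibble(df)
}

#' Write / read a pulse waveform CSV
#'
#' Format: a comment header `# fs_hz=<rate>` declaring the sampling rate,
#' then `time_s,amplitude` rows.
#'
#' @param waveform A `ppg_waveform` tibble.
#' @param path File path.
#' @return `write_waveform_csv()` returns `path` invisibly;
#'   `read_waveform_csv()` returns a `ppg_waveform` tibble.
#' @export
write_waveform_csv <- function(waveform, path) {
  fs <- attr(waveform, "fs_hz")
  if (is.null(fs)) fs <- 1 / median(diff(waveform$time_s))
  write_plain_csv(waveform[, c("time_s", "amplitude")], path,
                  sprintf("# fs_hz=%.15g", fs))
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^# *fs_hz=([0-9.eE+-]+)$", first))[[1]]
  if (length(m) != 2L) {
    abort(sprintf("'%s' line 1: expected header '# fs_hz=<rate>', got '%s'",
                  path, first))
  }
  df <- parse_csv_file(path, skip = 1L)
  if (!all(c("time_s", "amplitude") %in% names(df))) {
    abort(sprintf("'%s': expected columns time_s,amplitude", path))
  }
  new_ppg_waveform(df, as.numeric(m[2]))
}

#' Write / read a beat-time CSV (column `beat_time_s`)
#'
#' @param beats Tibble with `beat_time_s`.
#' @param path File path.
#' @return The path (write) or a validated beat tibble (read).
#' @export
write_beats_csv <- function(beats, path) {
  write_plain_csv(tibble(beat_time_s = beat_times(beats)), path)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  df <- parse_csv_file(path)
  if (!"beat_time_s" %in% names(df)) {
    abort(sprintf("'%s': expected column beat_time_s", path))
  }
  if (nrow(df) > 1L && any(diff(df$beat_time_s) <= 0)) {
    abort(sprintf("'%s': beat times must be strictly increasing", path))
  }
  tibble(beat_time_s = df$beat_time_s)
}

#' Write / read an interval CSV (`anchor_time_s,pp_ms,flag`)
#'
#' @param intervals Interval tibble.
#' @param path File path.
#' @return The path (write) or a validated interval tibble (read).
#' @export
write_intervals_csv <- function(intervals, path) {
  check_intervals(intervals)
  df <- intervals
  if (!"flag" %in% names(df)) df$flag <- FALSE
  df$flag <- as.integer(df$flag)
  write_plain_csv(df[, c("anchor_time_s", "pp_ms", "flag")], path)
  invisible(path)
}

#' @rdname write_intervals_csv
#' @export
read_intervals_csv <- function(path) {
  df <- parse_csv_file(path)
  need <- c("anchor_time_s", "pp_ms")
  if (!all(need %in% names(df))) {
    abort(sprintf("'%s': expected columns anchor_time_s,pp_ms[,flag]", path))
  }
  if (!"flag" %in% names(df)) df$flag <- 0L
  if (nrow(df) > 1L && any(diff(df$anchor_time_s) <= 0)) {
    abort(sprintf("'%s': anchor times must be strictly increasing", path))
  }
  if (any(df$pp_ms <= 0)) abort(sprintf("'%s': pp_ms must be > 0", path))
  tibble(anchor_time_s = df$anchor_time_s, pp_ms = df$pp_ms,
         flag = as.logical(df$flag))
}

#' Write / read a time-resolved HRV CSV
#'
#' Columns: `window_center_s,hr_bpm,lf_ms2,hf_ms2,lfhf`.
#'
#' @param hrv An `hrv_series` tibble.
#' @param path File path.
#' @return The path (write) or an `hrv_series` tibble (read).
#' @export
write_hrv_csv <- function(hrv, path) {
  cols <- c("window_center_s", "hr_bpm", "lf_ms2", "hf_ms2", "lfhf")
  write_plain_csv(hrv[, cols], path)
  invisible(path)
}

#' @rdname write_hrv_csv
#' @export
read_hrv_csv <- function(path) {
  df <- parse_csv_file(path)
  cols <- c("window_center_s", "hr_bpm", "lf_ms2", "hf_ms2", "lfhf")
  if (!all(cols %in% names(df))) {
    abort(sprintf("'%s': expected columns %s", path,
                  paste(cols, collapse = ",")))
  }
  out <- as_tibble(df[, cols])
  class(out) <- c("hrv_series", class(out))
  out
}

#' Write / read a labeled feature cohort CSV
#'
#' Columns: `subject_id,label`, then the nine canonical features.
#'
#' @param data Cohort tibble.
#' @param path File path.
#' @return The path (write) or a validated cohort tibble (read).
#' @export
write_cohort_csv <- function(data, path) {
  check_cohort(data, require_both = FALSE)
  cols <- c("subject_id", "label", canonical_feature_order())
  if (!"subject_id" %in% names(data)) {
    data$subject_id <- sprintf("s%03d", seq_len(nrow(data)))
  }
  write_plain_csv(data[, cols], path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- parse_csv_file(path)
  if (nrow(df) == 0L) abort(sprintf("'%s': no rows in cohort file", path))
  cols <- c("subject_id", "label", canonical_feature_order())
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("'%s': missing column(s) %s", path,
                  paste(missing, collapse = ",")))
  }
  out <- as_tibble(df[, cols])
  check_cohort(out, require_both = FALSE)
  out
}

#' Write / read a logit screening model as JSON
#'
#' Format: `{"A": [[..3 rows..]], "constant": <num>,
#' "feature_order": [...], "orientation": "healthy_high"}`. Coefficients
#' round-trip exactly (full double precision).
#'
#' @param model A `logit_model`.
#' @param path File path.
#' @return The path (write) or a `logit_model` (read).
#' @export
write_model_json <- function(model, path) {
  if (!inherits(model, "logit_model")) abort("`model` must be a logit_model")
  obj <- list(A = unname(apply(model$A, 1, as.numeric, simplify = FALSE)),
              constant = model$constant,
              feature_order = model$feature_order,
              orientation = model$orientation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    abort(sprintf("malformed model JSON '%s': %s", path,
                                  conditionMessage(e)))
                  })
  need <- c("A", "constant", "feature_order", "orientation")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    abort(sprintf("'%s': missing field(s) %s", path,
                  paste(missing, collapse = ",")))
  }
  A <- obj$A
  if (is.list(A)) A <- do.call(rbind, lapply(A, as.numeric))
  if (!is.matrix(A) || !all(dim(A) == c(3L, 3L))) {
    abort(sprintf("'%s': field A must be a 3x3 matrix (3 rows of 3)", path))
  }
  logit_model(A,
              constant = obj$constant,
              feature_order = obj$feature_order,
              orientation = obj$orientation)
}
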