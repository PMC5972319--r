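# Pipeline configuration schema: allowed keys and the type check applied to
# each. Unknown keys are rejected before any computation starts.
pipeline_schema <- function() {
  num <- function(x) is.numeric(x) && all(is.finite(x))
  list(
    input_waveform_csv = is.character,
    phase_boundaries_s = function(x) num(x) && length(x) == 4 &&
      all(diff(x) > 0),
    detector = function(x) is.list(x) &&
      all(names(x) %in% c("detrend_window_s", "threshold_window_s",
                          "threshold_quantile", "refractory_s")),
    artifact = function(x) is.list(x) &&
      all(names(x) %in% c("min_ms", "max_ms", "max_deviation",
                          "max_flagged_frac")),
    model_json = is.character,
    threshold = num,
    seed = function(x) is.numeric(x) && length(x) == 1,
    out_dir = is.character,
    log_level = function(x) x %in% c("quiet", "info")
  )
}

#' Default end-to-end pipeline configuration
#'
#' @return A named list accepted by [run_screening_pipeline()]: the 320-s
#'   three-phase schedule, default detector and artifact parameters, the
#'   frozen reference model and a zero classification threshold.
#' @export
default_pipeline_config <- function() {
  list(phase_boundaries_s = c(0, 100, 200, 320),
       detector = list(), artifact = list(),
       threshold = 0, log_level = "quiet")
}

#' Validate a pipeline configuration against the schema
#'
#' Rejects unknown keys and type-invalid values with the offending name, so
#' no computation starts on a config the pipeline cannot honor.
#'
#' @param config Named list.
#' @return The config, invisibly, if valid.
#' @export
validate_pipeline_config <- function(config) {
  schema <- pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  for (k in names(config)) {
    if (!isTRUE(schema[[k]](config[[k]]))) {
      abort(sprintf("config key '%s' failed validation", k))
    }
  }
  invisible(config)
}

pipeline_log <- function(level, ...) {
  if (identical(level, "info")) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
  }
}

#' Run the full screening pipeline on one recording
#'
#' Executes the complete chain on a pulse waveform: peak detection,
#' interval construction, artifact cleaning, 4-Hz tachogram resampling over
#' the recording extent, sliding-window spectral HRV, phase-feature
#' extraction, and logit scoring/classification with the frozen reference
#' model (or a model file named in the config). All intermediate artifacts
#' are written to `out_dir` when one is configured.
#'
#' @param config Named list validated by [validate_pipeline_config()]; at
#'   minimum `input_waveform_csv` or a `waveform` argument.
#' @param waveform Optional in-memory `ppg_waveform` (overrides the file
#'   input).
#' @return A list of class `screening_run`: `score`, `label`, `features`,
#'   `hrv`, `intervals`, `beats`, and the resolved `config`.
#' @export
run_screening_pipeline <- function(config = default_pipeline_config(),
                                   waveform = NULL) {
  config <- modifyList(default_pipeline_config(), config)
  validate_pipeline_config(config)
  lvl <- config$log_level
  pipeline_log(lvl, "resolved config: %s",
               jsonlite::toJSON(config[setdiff(names(config), "waveform")],
                                auto_unbox = TRUE))
  if (is.null(waveform)) {
    if (is.null(config$input_waveform_csv)) {
      abort("no input: supply `waveform` or config$input_waveform_csv")
    }
    waveform <- read_waveform_csv(config$input_waveform_csv)
  }
  bounds <- config$phase_boundaries_s
  total <- bounds[4]
  extent <- max(waveform$time_s) - min(waveform$time_s)
  if (extent < total - 1e-9) {
    abort(sprintf(
      "recording covers %.1f s but the phase schedule requires %.1f s",
      extent, total))
  }
  pipeline_log(lvl, "detecting pulse peaks")
  beats <- do.call(detect_pulse_peaks, c(list(waveform), config$detector))
  intervals <- beats_to_intervals(beats)
  intervals <- do.call(clean_intervals, c(list(intervals), config$artifact))
  pipeline_log(lvl, "%d beats, %d intervals (%d repaired)",
               nrow(beats), nrow(intervals), sum(intervals$flag))
  tach <- resample_tachogram(intervals, start_s = bounds[1], end_s = total)
  hrv <- sliding_hrv(tach, intervals)
  features <- phase_features(hrv, phase_definition(bounds))
  model <- if (!is.null(config$model_json)) {
    read_model_json(config$model_json)
  } else {
    reference_model()
  }
  score <- logit_score(features, model)
  label <- classify(score, config$threshold)
  pipeline_log(lvl, "logit score %.3f -> %s", score, label)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_beats_csv(beats, p("beats.csv"))
    write_intervals_csv(intervals, p("intervals.csv"))
    write_hrv_csv(hrv, p("hrv.csv"))
    write_plain_csv(features, p("features.csv"))
    jsonlite::write_json(
      list(score = score, label = label,
           features = as.list(features), threshold = config$threshold),
      p("score.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(score = score, label = label, features = features,
                 hrv = hrv, intervals = intervals, beats = beats,
                 config = config),
            class = "screening_run")
}

#' @export
print.screening_run <- function(x, ...) {
  cat(sprintf(
    "Screening run: %d beats, %d HRV windows, logit score %.3f -> %s\n",
    nrow(x$beats), nrow(x$hrv), x$score, x$label))
  invisible(x)
}
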