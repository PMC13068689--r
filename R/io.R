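# Plain-text I/O contracts: RR series and ECG traces as two-column CSV
# (with a JSON sidecar carrying the sampling rate and metadata), beat
# annotations, and cohort manifests.

#' Write / read an RR series as CSV
#'
#' Two columns: `time_s` (beat time of the interval's closing beat) and
#' `rr_ms`.
#'
#' @param beats A `beat_series`.
#' @param path Output CSV path.
#' @return `write_rr_csv` returns `path` invisibly; `read_rr_csv` returns a
#'   `beat_series` with `source = "annotated"`.
#' @export
write_rr_csv <- function(beats, path) {
  df <- data.frame(
    time_s = beats$beat_times[-1],
    rr_ms = beats$rr_ms,
    corrected = as.integer(beats$corrected)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "rr_ms") %in% names(df)))
  first <- df$time_s[1] - df$rr_ms[1] / 1000
  beat_series(
    c(first, df$time_s),
    rr_ms = df$rr_ms,
    corrected = if ("corrected" %in% names(df)) df$corrected == 1 else NULL,
    source = "annotated"
  )
}

#' Write / read an ECG record as CSV plus JSON sidecar
#'
#' The CSV has `time_s` and `mv` columns; the sidecar (`<path>.json`)
#' carries the sampling rate, start time, and beat count.
#'
#' @param ecg An `ecg_record`.
#' @param path Output CSV path.
#' @return `write_ecg_csv` returns `path` invisibly; `read_ecg_csv` returns
#'   an `ecg_record`.
#' @export
write_ecg_csv <- function(ecg, path) {
  t <- ecg$start_time + (seq_along(ecg$samples) - 1L) / ecg$fs
  utils::write.csv(data.frame(time_s = t, mv = ecg$samples), path, row.names = FALSE)
  jsonlite::write_json(
    list(fs = ecg$fs, start_time = ecg$start_time, n_beats = ecg$n_beats),
    paste0(path, ".json"),
    auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_ecg_csv
#' @export
read_ecg_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(
      samples = df$mv,
      fs = meta$fs,
      start_time = meta$start_time %||% df$time_s[1],
      n_beats = meta$n_beats %||% NA_integer_
    ),
    class = "ecg_record"
  )
}

#' Write a cohort manifest
#'
#' @param cohort A cohort list (see [generate_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  utils::write.csv(cohort$manifest, path, row.names = FALSE)
  invisible(path)
}
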