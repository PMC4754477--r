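#' Single-lead ECG segment
#'
#' A light record holding one single-lead ECG excerpt: the amplitude series,
#' its sampling frequency, the lead it was taken from, an optional rhythm
#' label and a provenance tag. All downstream verbs (preprocessing, feature
#' extraction, confirmation) consume this type, either directly or inside a
#' list-column of a tibble.
#'
#' @param samples Numeric vector of amplitudes (mV before normalization,
#'   arbitrary units after). Must be finite everywhere.
#' @param fs Sampling frequency in Hz (> 0).
#' @param lead Lead identifier (`"I"`, `"II"`, `"V1"`, ..., or
#'   `"synthetic"`).
#' @param label Rhythm-class tag: one of `"NSR"`, `"CHF"`, `"AF"`, `"PEB"`,
#'   `"unknown"`.
#' @param source_id Free-text provenance (record name or generator seed
#'   string).
#' @return An object of class `ecg_segment`.
#' @examples
#' seg <- ecg_segment(sin(2 * pi * 1.2 * seq(0, 10, by = 1 / 250)), fs = 250)
#' seg
#' @export
ecg_segment <- function(samples, fs, lead = "synthetic", label = "unknown",
                        source_id = "") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("ecg_segment: 'samples' is empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("ecg_segment: 'samples' contains non-finite values (NaN/Inf/NA)",
         call. = FALSE)
  }
  fs <- as.numeric(fs)
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("ecg_segment: 'fs' must be a single positive number", call. = FALSE)
  }
  label <- match.arg(label, c("NSR", "CHF", "AF", "PEB", "unknown"))
  structure(
    list(samples = samples, fs = fs, lead = as.character(lead),
         label = label, source_id = as.character(source_id)),
    class = "ecg_segment"
  )
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf(
    "<ecg_segment> %d samples @ %g Hz (%.2f s), lead %s, label %s%s\n",
    length(x$samples), x$fs, length(x$samples) / x$fs, x$lead, x$label,
    if (nzchar(x$source_id)) paste0(", source ", x$source_id) else ""
  ))
  invisible(x)
}

#' @export
length.ecg_segment <- function(x) length(x$samples)

#' Duration of a segment in seconds
#' @param seg An [ecg_segment].
#' @return Duration in seconds.
#' @export
segment_duration <- function(seg) length(seg$samples) / seg$fs

#' @export
#' @importFrom tibble as_tibble
as_tibble.ecg_segment <- function(x, ...) {
  tibble::tibble(
    time = (seq_along(x$samples) - 1) / x$fs,
    amplitude = x$samples
  )
}

#' Cut a long record into fixed-duration segments
#'
#' Splits a record into consecutive non-overlapping windows of exactly
#' `duration_s * fs` samples; the trailing remainder is discarded. Ten-second
#' windows (roughly 12 beats at typical rates) are the unit every other verb
#' in the package operates on.
#'
#' @param record An [ecg_segment] (typically a long excerpt).
#' @param duration_s Window length in seconds (default 10).
#' @return A tibble with columns `source_id`, `label`, `start_s` and a
#'   list-column `segment` of [ecg_segment]s; zero rows if the record is
#'   shorter than one window.
#' @examples
#' rec <- ecg_segment(rnorm(250 * 25), fs = 250, source_id = "rec1")
#' segment_record(rec, duration_s = 10)
#' @export
segment_record <- function(record, duration_s = 10) {
  stopifnot(inherits(record, "ecg_segment"), duration_s > 0)
  win <- round(duration_s * record$fs)
  k <- length(record$samples) %/% win
  if (k == 0L) {
    return(tibble::tibble(source_id = character(), label = character(),
                          start_s = numeric(), segment = list()))
  }
  segs <- lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * win + 1L):(i * win)
    ecg_segment(record$samples[idx], fs = record$fs, lead = record$lead,
                label = record$label,
                source_id = sprintf("%s#%02d", record$source_id, i))
  })
  tibble::tibble(
    source_id = vapply(segs, function(s) s$source_id, character(1)),
    label = record$label,
    start_s = (seq_len(k) - 1) * win / record$fs,
    segment = segs
  )
}
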