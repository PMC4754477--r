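#' Read a single-lead ECG segment from disk
#'
#' Reads either a two-column CSV (`time,amplitude`; header optional; the
#' time column is ignored unless `fs` is missing, in which case it is used
#' to infer the sampling rate) or a WFDB record (PhysioNet `.hea`/`.dat`
#' dialect, formats 16 and 212). Returns the raw, unnormalized segment with
#' `fs` taken from the header (WFDB) or from `fs`/the time column (CSV).
#'
#' @param path File path: the CSV file, or the WFDB `.hea` header (or its
#'   basename).
#' @param format `"auto"` (by extension), `"csv"` or `"wfdb"`.
#' @param lead Lead/signal selector. For WFDB, either a signal name as in
#'   the header or a 1-based channel index; an absent lead is an error. For
#'   CSV (single channel) it only tags the result.
#' @param fs Sampling frequency in Hz; required for CSV files without a
#'   usable time column.
#' @param label Optional rhythm label to attach.
#' @return An [ecg_segment].
#' @seealso [write_ecg_csv()], [write_wfdb()]
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb"), lead = NULL,
                     fs = NULL, label = "unknown") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(hea|dat)$", path)) "wfdb" else "csv"
  }
  switch(format,
    csv = read_ecg_csv(path, lead = lead %||% "unknown", fs = fs,
                       label = label),
    wfdb = read_wfdb(path, lead = lead, label = label)
  )
}

read_ecg_csv <- function(path, lead = "unknown", fs = NULL,
                         label = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^\\s*[-+0-9.eE]+\\s*,", first)
  df <- utils::read.csv(path, header = has_header,
                        col.names = c("time", "amplitude"))
  if (!is.numeric(df$amplitude) || anyNA(df$amplitude) ||
      !all(is.finite(df$amplitude))) {
    stop("CSV format error in '", path,
         "': column 'amplitude' contains missing or non-numeric values",
         call. = FALSE)
  }
  if (is.null(fs)) {
    if (!is.numeric(df$time) || nrow(df) < 2L || anyNA(df$time)) {
      stop("CSV format error in '", path,
           "': cannot infer fs, column 'time' unusable and no fs supplied",
           call. = FALSE)
    }
    dt <- stats::median(diff(df$time))
    if (!is.finite(dt) || dt <= 0) {
      stop("CSV format error in '", path,
           "': column 'time' is not increasing", call. = FALSE)
    }
    fs <- 1 / dt
  }
  ecg_segment(df$amplitude, fs = fs, lead = lead, label = label,
              source_id = basename(path))
}

#' Write a segment to a two-column CSV
#'
#' @param seg An [ecg_segment].
#' @param path Output file path.
#' @param digits Significant digits for the amplitude column (default 17,
#'   i.e. round-trip exact for doubles).
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(seg, path, digits = 17) {
  stopifnot(inherits(seg, "ecg_segment"))
  df <- data.frame(
    time = format((seq_along(seg$samples) - 1) / seg$fs, digits = digits),
    amplitude = format(seg$samples, digits = digits)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- minimal WFDB (PhysioNet) support: formats 16 and 212 ------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec) < 4L) {
    stop("WFDB format error in '", hea_path,
         "': record line needs <name> <nsig> <fs> <nsamp>", call. = FALSE)
  }
  nsig <- as.integer(rec[2])
  fs <- as.numeric(sub("/.*", "", rec[3]))
  nsamp <- as.integer(rec[4])
  if (any(is.na(c(nsig, fs, nsamp)))) {
    stop("WFDB format error in '", hea_path,
         "': non-numeric nsig/fs/nsamp field", call. = FALSE)
  }
  sig <- lapply(lines[1 + seq_len(nsig)], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 2L) {
      stop("WFDB format error in '", hea_path,
           "': signal line needs at least <file> <format>", call. = FALSE)
    }
    gain <- if (length(f) >= 3) as.numeric(sub("[(/].*", "", f[3])) else 200
    baseline <- if (length(f) >= 3 && grepl("\\(", f[3])) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", f[3]))
    } else 0
    list(file = f[1], format = as.integer(sub("[x:+].*", "", f[2])),
         gain = if (is.na(gain) || gain == 0) 200 else gain,
         baseline = baseline,
         name = if (length(f) >= 9) f[length(f)] else NA_character_)
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_wfdb <- function(path, lead = NULL, label = "unknown") {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(sub("\\.dat$", "", path), ".hea")
  if (!file.exists(hea_path)) stop("file not found: ", hea_path, call. = FALSE)
  hdr <- parse_wfdb_header(hea_path)
  names_avail <- vapply(hdr$signals, function(s)
    if (is.na(s$name)) "" else s$name, character(1))
  ch <- if (is.null(lead)) {
    1L
  } else if (is.numeric(lead)) {
    as.integer(lead)
  } else {
    match(lead, names_avail)
  }
  if (is.na(ch) || ch < 1L || ch > hdr$nsig) {
    stop("lead '", lead, "' not found in record '", hdr$record,
         "' (available: ",
         paste(names_avail[nzchar(names_avail)], collapse = ", "), ")",
         call. = FALSE)
  }
  dat_path <- file.path(dirname(hea_path), hdr$signals[[ch]]$file)
  if (!file.exists(dat_path)) stop("file not found: ", dat_path, call. = FALSE)
  fmt <- hdr$signals[[ch]]$format
  raw_all <- readBin(dat_path, "raw", file.size(dat_path))
  adc <- switch(as.character(fmt),
    "16" = {
      v <- readBin(raw_all, "integer", n = hdr$nsamp * hdr$nsig, size = 2L,
                   signed = TRUE, endian = "little")
      matrix(v, ncol = hdr$nsig, byrow = TRUE)[, ch]
    },
    "212" = {
      if (hdr$nsig > 2L) {
        stop("WFDB format error: format 212 supported for <= 2 signals",
             call. = FALSE)
      }
      b <- as.integer(raw_all)
      ntrip <- length(b) %/% 3L
      b1 <- b[3 * seq_len(ntrip) - 2L]
      b2 <- b[3 * seq_len(ntrip) - 1L]
      b3 <- b[3 * seq_len(ntrip)]
      s1 <- b1 + bitwShiftL(bitwAnd(b2, 15L), 8L)
      s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4L), 15L), 8L)
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      if (hdr$nsig == 1L) {
        as.vector(rbind(s1, s2))[seq_len(hdr$nsamp)]
      } else if (ch == 1L) s1[seq_len(hdr$nsamp)] else s2[seq_len(hdr$nsamp)]
    },
    stop("WFDB format error: unsupported signal format ", fmt, call. = FALSE)
  )
  sig <- hdr$signals[[ch]]
  ecg_segment((adc - sig$baseline) / sig$gain, fs = hdr$fs,
              lead = if (nzchar(names_avail[ch])) names_avail[ch] else as.character(ch),
              label = label, source_id = hdr$record)
}

#' Write a segment as a WFDB record (format 16)
#'
#' Writes a `.hea`/`.dat` pair in the PhysioNet dialect, quantizing
#' amplitudes with the given gain. Intended for interoperability checks and
#' for exporting synthetic segments; quantization limits round-trip
#' fidelity to `1 / (2 * gain)`.
#'
#' @param seg An [ecg_segment].
#' @param record_dir Directory to write into.
#' @param record_name Record name (basename of `.hea`/`.dat`).
#' @param gain ADC units per millivolt (default 1000).
#' @return The `.hea` path, invisibly.
#' @export
write_wfdb <- function(seg, record_dir, record_name, gain = 1000) {
  stopifnot(inherits(seg, "ecg_segment"))
  adc <- as.integer(round(seg$samples * gain))
  if (any(abs(adc) > 32767L)) {
    stop("amplitude overflow at gain ", gain, call. = FALSE)
  }
  hea <- file.path(record_dir, paste0(record_name, ".hea"))
  dat <- paste0(record_name, ".dat")
  writeLines(c(
    sprintf("%s 1 %g %d", record_name, seg$fs, length(adc)),
    sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s", dat, gain, adc[1], seg$lead)
  ), hea)
  con <- file(file.path(record_dir, dat), "wb")
  on.exit(close(con))
  writeBin(adc, con, size = 2L, endian = "little")
  invisible(hea)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
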