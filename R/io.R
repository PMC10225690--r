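#' Read an LFP recording from disk
#'
#' CSV recordings carry their metadata in `#`-prefixed header lines
#' (`# fs_hz:`, `# units:`, `# label:`) followed by either a single `mv`
#' column or two columns `time_s, mv`.  When a `time_s` column is present the
#' sampling rate is inferred from it and the stamps are checked for
#' uniformity (relative jitter above 1e-6 is an error).  EDF files are read
#' with the package's minimal single-channel EDF reader.
#'
#' @param path file to read.
#' @param format `"csv"` or `"edf"`; by default guessed from the extension.
#' @return an [lfp_recording].
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, csv = read_recording_csv(path), edf = read_edf(path))
}

read_recording_csv <- function(path) {
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (length(head_lines) == 0L) stop("empty recording file: ", path)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 3L) meta[[m[2L]]] <- trimws(m[3L])
  }
  n_skip <- length(meta_lines)
  if (n_skip >= length(head_lines)) stop("recording file has no data rows: ", path)
  dt <- data.table::fread(path, skip = n_skip, header = TRUE)
  if (nrow(dt) == 0L) stop("recording file has no data rows: ", path)
  label <- if (!is.null(meta$label)) meta$label else ""
  if ("time_s" %in% names(dt) && "mv" %in% names(dt)) {
    tt <- dt$time_s
    if (nrow(dt) < 2L) stop("cannot infer fs from a single time stamp")
    dts <- diff(tt)
    dt_med <- stats::median(dts)
    if (dt_med <= 0 || any(abs(dts - dt_med) > 1e-6 * dt_med + 1e-12)) {
      stop("non-uniform time stamps in ", path)
    }
    lfp_recording(dt$mv, fs = 1 / dt_med, start_time = tt[1L], label = label)
  } else if ("mv" %in% names(dt)) {
    if (is.null(meta$fs_hz)) {
      stop("single-column CSV requires a '# fs_hz:' header line")
    }
    start_time <- if (!is.null(meta$start_time_s)) as.numeric(meta$start_time_s) else 0
    lfp_recording(dt$mv, fs = as.numeric(meta$fs_hz),
                  start_time = start_time, label = label)
  } else {
    stop("CSV must contain an 'mv' column (optionally with 'time_s')")
  }
}

#' Write an LFP recording to disk
#'
#' @param rec an [lfp_recording].
#' @param path destination file.
#' @param format `"csv"` or `"edf"`; by default guessed from the extension.
#' @param time_column for CSV, also write an explicit `time_s` column.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf"),
                            time_column = FALSE) {
  stopifnot(inherits(rec, "lfp_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(write_edf(rec, path))
  header <- c(sprintf("# fs_hz: %.10g", rec$fs),
              "# units: mV",
              sprintf("# start_time_s: %.10g", rec$start_time),
              sprintf("# label: %s", rec$label))
  writeLines(header, path)
  if (time_column) {
    dt <- data.table::data.table(
      time_s = rec$start_time + (seq_along(rec$samples) - 1) / rec$fs,
      mv = rec$samples)
  } else {
    dt <- data.table::data.table(mv = rec$samples)
  }
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

# --- minimal EDF (European Data Format) support ----------------------------
# Single-channel continuous EDF: 256-byte fixed header, 256-byte signal
# header, one data record of 16-bit little-endian integers.  Covers
# round-tripping recordings through the standard electrophysiology container;
# annotations, multiple channels and EDF+ extensions are out of scope.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  n <- length(rec$samples)
  pmin_ <- min(rec$samples); pmax_ <- max(rec$samples)
  if (pmax_ <= pmin_) { pmax_ <- pmin_ + 1 }  # constant trace: avoid 0 gain
  dmin <- -32768; dmax <- 32767
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  dig <- as.integer(pmax(dmin, pmin(dmax, round((rec$samples - pmin_) / gain) + dmin)))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)                                   # version
  wr("X X X X", 80)                            # patient id
  wr(paste("Startdate X X X X", rec$label), 80)  # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)         # start date/time
  wr(as.character(256L + 256L), 8)             # header bytes
  wr("", 44)                                   # reserved
  wr("1", 8)                                   # number of data records
  wr(sprintf("%.6g", n / rec$fs), 8)           # record duration [s]
  wr("1", 4)                                   # number of signals
  wr("LFP", 16)                                # label
  wr("intracranial electrode", 80)             # transducer
  wr("mV", 8)                                  # physical dimension
  wr(sprintf("%.6g", pmin_), 8)
  wr(sprintf("%.6g", pmin_ + gain * (dmax - dmin)), 8)
  wr(as.character(dmin), 8); wr(as.character(dmax), 8)
  wr("LP:600Hz", 80)                           # prefiltering
  wr(as.character(n), 8)                       # samples per record
  wr("", 32)                                   # reserved
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  rd(80); recording_id <- rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_records <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns != 1L) stop("only single-channel EDF files are supported")
  rd(16); rd(80); rd(8)
  pmin_ <- as.numeric(rd(8)); pmax_ <- as.numeric(rd(8))
  dmin <- as.numeric(rd(8)); dmax <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8))
  rd(32)
  seek(con, header_bytes)
  dig <- readBin(con, "integer", n = n_records * spr, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dig) == 0L) stop("EDF file contains no samples: ", path)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  mv <- pmin_ + (dig - dmin) * gain
  fs <- spr / rec_dur
  label <- sub("^Startdate X X X X\\s*", "", recording_id)
  lfp_recording(mv, fs = fs, label = trimws(label))
}

# --- event tables ----------------------------------------------------------

#' Write an event table
#'
#' Tab-separated table with columns `kind`, `start_s`, `end_s`; times are
#' written with millisecond precision.  Events must already be sorted by
#' start time.
#'
#' @param events a data.frame with columns `kind`, `start`, `end`
#'   (see [event_interval()]).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events), all(c("kind", "start", "end") %in% names(events)))
  if (nrow(events) > 1L && is.unsorted(events$start)) {
    stop("events must be sorted by start time")
  }
  lines <- c("kind\tstart_s\tend_s",
             sprintf("%s\t%.3f\t%.3f", events$kind, events$start, events$end))
  writeLines(lines, path)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path file to read.
#' @return a data.frame with columns `kind`, `start`, `end`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(dt) == 0L) return(event_table())
  event_table(dt$kind, dt$start_s, dt$end_s)
}

# --- flat key = value configuration files ----------------------------------

#' Read a flat key = value configuration file
#'
#' One `key = value` assignment per line; `#` starts a comment.  Values may
#' be numbers, strings, comma-separated numeric lists, or comma-separated
#' `start:end` interval pairs (parsed to a list of length-2 numeric vectors).
#'
#' @param path file to read.
#' @return a named list of parsed values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1L]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    out[[m[2L]]] <- parse_config_value(trimws(m[3L]))
  }
  out
}

parse_config_value <- function(v) {
  v <- gsub("^\\[|\\]$", "", v)  # tolerate optional [...] wrapping
  if (!nzchar(v)) return(NULL)
  parts <- trimws(strsplit(v, ",")[[1L]])
  if (all(grepl(":", parts))) {
    return(lapply(parts, function(p) as.numeric(strsplit(p, ":")[[1L]])))
  }
  num <- suppressWarnings(as.numeric(parts))
  if (!anyNA(num)) return(num)
  if (length(parts) == 1L) {
    if (parts %in% c("true", "TRUE")) return(TRUE)
    if (parts %in% c("false", "FALSE")) return(FALSE)
    return(gsub('^"|"$', "", parts))
  }
  parts
}
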