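#' LFP recording container
#'
#' A uniformly sampled single-channel local field potential trace.  Amplitude
#' is stored in millivolts; `fs` is the sampling rate in Hz.  `start_time`
#' anchors the first sample on the recording clock so that windows cut out of
#' a longer trace keep absolute event times.  Sample index `i` (1-based)
#' covers the half-open interval `[start_time + (i-1)/fs, start_time + i/fs)`.
#'
#' @param samples numeric vector of amplitudes (mV); must be finite and
#'   non-empty.
#' @param fs sampling rate in Hz, positive.
#' @param start_time time of the first sample in seconds (default 0).
#' @param label free-text channel/recording label.
#' @return an object of class `lfp_recording`.
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 8 * seq(0, 1, by = 1 / 2048)), fs = 2048)
#' rec_duration(rec)
#' @export
lfp_recording <- function(samples, fs, start_time = 0, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("recording must contain at least one sample")
  }
  if (!all(is.finite(samples))) {
    stop("recording samples must be finite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number")
  }
  structure(
    list(samples = samples, fs = as.numeric(fs),
         start_time = as.numeric(start_time), label = as.character(label)[1L]),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d samples @ %g Hz  (%.3f s, t0 = %.3f s)\n",
              length(x$samples), x$fs, rec_duration(x), x$start_time))
  cat(sprintf("  amplitude range [%.4g, %.4g] mV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `lfp_recording`.
#' @return duration in seconds (`length(samples) / fs`).
#' @export
rec_duration <- function(rec) {
  stopifnot(inherits(rec, "lfp_recording"))
  length(rec$samples) / rec$fs
}

#' Cut a time window out of a recording
#'
#' Extracts samples covering the half-open interval `[from, to)` on the
#' recording clock.  The result keeps its absolute `start_time`.
#'
#' @param rec an `lfp_recording`.
#' @param from,to window bounds in seconds (absolute times).
#' @return an `lfp_recording` for the window.
#' @export
rec_window <- function(rec, from, to) {
  stopifnot(inherits(rec, "lfp_recording"), to > from)
  i0 <- round((from - rec$start_time) * rec$fs)
  i1 <- round((to - rec$start_time) * rec$fs)
  if (i0 < 0 || i1 > length(rec$samples)) {
    stop(sprintf("window [%g, %g) outside recording [%g, %g)",
                 from, to, rec$start_time, rec$start_time + rec_duration(rec)))
  }
  lfp_recording(rec$samples[(i0 + 1L):i1], rec$fs,
                start_time = from, label = rec$label)
}

#' Event interval
#'
#' A labelled half-open time interval `[start, end)` in seconds.  Kinds are
#' `seizure`, `lull` (post-ictal low-amplitude period) and `iis` (inter-ictal
#' spike).  IIS events must be shorter than one second.
#'
#' @param kind one of `"seizure"`, `"lull"`, `"iis"`.
#' @param start,end interval bounds in seconds, `end >= start`.
#' @return a one-row `data.frame` with columns `kind`, `start`, `end`.
#' @export
event_interval <- function(kind, start, end) {
  kind <- match.arg(kind, c("seizure", "lull", "iis"))
  if (end < start) stop("event end must be >= start")
  if (kind == "iis" && (end - start) >= 1) {
    stop("iis events must be shorter than 1 s")
  }
  data.frame(kind = kind, start = as.numeric(start), end = as.numeric(end),
             stringsAsFactors = FALSE)
}

event_table <- function(kind = character(), start = numeric(), end = numeric()) {
  data.frame(kind = as.character(kind), start = as.numeric(start),
             end = as.numeric(end), stringsAsFactors = FALSE)
}
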