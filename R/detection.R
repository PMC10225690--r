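#' Downsample a recording by an integer factor
#'
#' Anti-alias filters (zero-phase Butterworth, order 8, cutoff
#' `0.4 * target_fs`) and then decimates.  Seizure detection operates on a
#' 256 Hz version of the signal.
#'
#' @param rec an [lfp_recording].
#' @param target_fs target sampling rate; `rec$fs` must be an integer
#'   multiple of it.
#' @return an [lfp_recording] at `target_fs`.
#' @export
downsample <- function(rec, target_fs = 256) {
  stopifnot(inherits(rec, "lfp_recording"))
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("fs must be an integer multiple of target_fs")
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  lp <- signal::butter(8, (0.4 * target_fs) / (rec$fs / 2), type = "low")
  y <- signal::filtfilt(lp, rec$samples)
  idx <- seq(1L, length(y), by = ratio)
  lfp_recording(y[idx], fs = target_fs, start_time = rec$start_time,
                label = rec$label)
}

#' Per-epoch signal envelope (Max_wave / Min_wave)
#'
#' Splits a 256 Hz recording into non-overlapping 125 ms epochs of exactly
#' 32 samples and records the per-epoch maximum and minimum.  A trailing
#' partial epoch is dropped.
#'
#' @param rec256 an [lfp_recording] sampled at 256 Hz.
#' @return an `envelope_series`: list with `max_wave`, `min_wave`, `epoch_s`
#'   (0.125), `start_time`, and, after [hv_lv()], `hv` and `lv`.
#' @export
epoch_minmax <- function(rec256) {
  stopifnot(inherits(rec256, "lfp_recording"))
  if (abs(rec256$fs - 256) > 1e-9) stop("epoch_minmax expects a 256 Hz recording")
  n_ep <- floor(length(rec256$samples) / 32L)
  if (n_ep < 1L) stop("recording shorter than one 125 ms epoch")
  m <- matrix(rec256$samples[seq_len(n_ep * 32L)], nrow = 32L)
  structure(
    list(max_wave = apply(m, 2L, max), min_wave = apply(m, 2L, min),
         hv = NULL, lv = NULL, epoch_s = 0.125,
         start_time = rec256$start_time),
    class = "envelope_series"
  )
}

#' Correlated envelope functions HV and LV
#'
#' For epoch index i (1-based):
#' `HV[i] = min(max_wave[i], max(max_wave[i+1], max_wave[i+2]))` and
#' `LV[i] = max(min_wave[i], min(min_wave[i+1], min_wave[i+2]))`.
#' Looking forward across three consecutive epochs suppresses isolated
#' single-epoch noise transients.  The HV/LV series is two epochs shorter
#' than the envelope.
#'
#' @param env an `envelope_series` from [epoch_minmax()].
#' @return the same object with `hv` and `lv` filled in.
#' @export
hv_lv <- function(env) {
  stopifnot(inherits(env, "envelope_series"))
  n <- length(env$max_wave)
  if (n < 3L) stop("need at least 3 epochs for HV/LV")
  i <- seq_len(n - 2L)
  env$hv <- pmin(env$max_wave[i], pmax(env$max_wave[i + 1L], env$max_wave[i + 2L]))
  env$lv <- pmax(env$min_wave[i], pmin(env$min_wave[i + 1L], env$min_wave[i + 2L]))
  env
}

#' Metric3S: summed HV-LV range in a 5 s sliding window
#'
#' For each window start t = 0, 1, 2, ... s, sums `HV - LV` over the 40
#' epochs whose start lies in `[t, t + 5)`; windows extending past the end of
#' the record are omitted (epochs at the very tail without an HV value
#' contribute nothing).
#'
#' @param env an `envelope_series` with `hv`/`lv` filled ([hv_lv()]).
#' @return a `metric_series`: list with `values`, `start_times` (window start
#'   seconds on the recording clock), `window_s` (5) and `step_s` (1).
#' @export
metric3s <- function(env) {
  stopifnot(inherits(env, "envelope_series"))
  if (is.null(env$hv)) stop("call hv_lv() first")
  n_ep <- length(env$max_wave)
  dur <- n_ep * env$epoch_s
  if (dur < 5) stop("record must be at least 5 s long")
  d <- env$hv - env$lv
  d_pad <- c(d, numeric(n_ep - length(d)))
  starts <- 0:floor(dur - 5)
  ep_per_s <- as.integer(round(1 / env$epoch_s))
  ep_per_win <- 5L * ep_per_s
  cs <- c(0, cumsum(d_pad))
  i0 <- starts * ep_per_s
  vals <- cs[i0 + ep_per_win + 1L] - cs[i0 + 1L]
  structure(
    list(values = vals, start_times = env$start_time + starts,
         window_s = 5, step_s = 1),
    class = "metric_series"
  )
}

#' Fit two Gaussian components to an all-point histogram
#'
#' Builds an all-point histogram of `values` and models it as two normal
#' distributions.  With `method = "separate"` (the default) the values are
#' partitioned by a deterministic extreme-seeded 2-means split and one
#' Gaussian is least-squares fitted to each side of the histogram
#' independently; with `method = "joint"` the sum of two Gaussians is
#' fitted to the whole histogram at once.  Components are ordered so
#' `mean1 <= mean2`.  Bimodality is summarized by Ashman's D,
#' `D = |mean1 - mean2| / sqrt((sd1^2 + sd2^2)/2)`; D > 2 indicates two
#' separable modes and is required by the detectors before thresholding.
#'
#' @param values numeric vector (>= 100 values).
#' @param n_bins number of histogram bins (>= 20); default is the
#'   Freedman-Diaconis count clamped to 50-100 bins.
#' @param method `"separate"` (one Gaussian per histogram side) or
#'   `"joint"` (sum of two Gaussians).
#' @return a `bimodal_fit`: list with `mean1`, `sd1`, `amp1`, `mean2`,
#'   `sd2`, `amp2`, `d_stat`, `n_bins`, `converged`.
#' @export
fit_bimodal <- function(values, n_bins = NULL,
                        method = c("separate", "joint")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  if (length(values) < 100L) stop("need at least 100 values for the histogram fit")
  if (is.null(n_bins)) {
    # Freedman-Diaconis, clamped to [50, 100]: a rare high-amplitude mode
    # stretches the range and unclamped FD would dilute it to empty bins
    iqr <- stats::IQR(values)
    if (iqr > 0) {
      bw <- 2 * iqr / length(values)^(1 / 3)
      n_bins <- max(50L, min(100L, ceiling(diff(range(values)) / bw)))
    } else {
      n_bins <- 50L
    }
  }
  if (n_bins < 20L) stop("n_bins must be at least 20")

  fail <- function() {
    structure(list(mean1 = NA_real_, sd1 = NA_real_, amp1 = NA_real_,
                   mean2 = NA_real_, sd2 = NA_real_, amp2 = NA_real_,
                   d_stat = NA_real_, n_bins = n_bins, converged = FALSE),
              class = "bimodal_fit")
  }
  rng <- range(values)
  if (diff(rng) == 0) return(fail())
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts
  binw <- diff(breaks[1:2])

  # Split point between the components.  Primary rule: the dominant mode's
  # robust tail (median + 8 * MAD) -- everything beyond it belongs to the
  # second component, however little mass it carries (a rare seizure mode).
  # When nothing substantial lies beyond the tail (unimodal data, or two
  # comparable modes as in a half/half mixture where the MAD spans both),
  # fall back to the boundary of a deterministic extreme-seeded 2-means
  # partition, which then separates comparable modes and on unimodal data
  # yields two strongly overlapping components and a small D.
  med <- stats::median(values)
  madv <- stats::mad(values)
  split <- med + 8 * madv
  n2 <- sum(values >= split)
  if (madv <= 0 || n2 < max(5, 0.002 * length(values))) {
    km <- suppressWarnings(
      stats::kmeans(matrix(values, ncol = 1L),
                    centers = matrix(rng, ncol = 1L),
                    algorithm = "Lloyd", iter.max = 100L))
    split <- mean(km$centers)
  }
  lo_side <- values < split
  if (sum(lo_side) < 2L || sum(!lo_side) < 2L) return(fail())
  m_init <- c(mean(values[lo_side]), mean(values[!lo_side]))
  s_init <- vapply(list(values[lo_side], values[!lo_side]), function(vv) {
    s <- stats::sd(vv)
    if (!is.finite(s) || s < binw / 2) binw / 2 else s
  }, numeric(1))
  a_init <- vapply(seq_len(2L), function(j) {
    max(1, max(y[abs(x - m_init[j]) <= 2 * s_init[j]], na.rm = TRUE))
  }, numeric(1))

  lmfit <- function(par, fn, lower, upper) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par, fn = fn, lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) NULL else fit$par
  }
  gauss <- function(p, xx) p[1L] * exp(-(xx - p[2L])^2 / (2 * p[3L]^2))
  lo1 <- c(0, rng[1L] - diff(rng), binw / 10)
  hi1 <- c(Inf, rng[2L] + diff(rng), diff(rng))

  if (method == "separate") {
    left <- x < split
    if (sum(left) < 3L || sum(!left) < 3L) return(fail())
    # each component's mean is constrained to its own histogram side and its
    # SD to that side's width, so sparse far modes cannot send the fit off
    # to a runaway half-Gaussian ramp
    # The two components play different roles downstream and are estimated
    # accordingly.  The left (dominant, background) Gaussian must describe
    # the histogram CORE -- its mean +/- 3 SD sets the event thresholds --
    # so it is fitted to the counts by least squares, which a few percent of
    # contaminating windows (lulls, partial event overlap) cannot distort.
    # The right-most Gaussian must describe the event cluster as a whole --
    # its mean + SD is the spike threshold, which has to clear the cluster's
    # low sub-populations (after-waves, partial windows) -- so it is the
    # moment (maximum-likelihood) normal of the side's values.
    moments_par <- function(side_vals, s0) {
      s <- stats::sd(side_vals)
      if (!is.finite(s) || s < binw / 2) s <- max(s0, binw / 2)
      a <- length(side_vals) * binw / (sqrt(2 * pi) * s)
      c(max(a, 1), mean(side_vals), s)
    }
    p1 <- lmfit(c(a_init[1L], m_init[1L], s_init[1L]),
                function(p) y[left] - gauss(p, x[left]),
                c(0, rng[1L], binw / 10), c(Inf, split, split - rng[1L]))
    s1_m <- stats::sd(values[lo_side])
    if (is.null(p1) || p1[1L] < 0.5 ||
        (is.finite(s1_m) && s1_m > 0 && p1[3L] > 2.5 * s1_m)) {
      p1 <- moments_par(values[lo_side], s_init[1L])
    }
    p2 <- moments_par(values[!lo_side], s_init[2L])
    p <- c(p1, p2)
  } else {
    p <- lmfit(c(a_init[1L], m_init[1L], s_init[1L],
                 a_init[2L], m_init[2L], s_init[2L]),
               function(p) y - gauss(p[1:3], x) - gauss(p[4:6], x),
               c(lo1, lo1), c(hi1, hi1))
    if (is.null(p)) return(fail())
  }
  comp <- if (p[2L] <= p[5L]) c(0L, 3L) else c(3L, 0L)
  a1 <- p[comp[1L] + 1L]; m1 <- p[comp[1L] + 2L]; s1 <- abs(p[comp[1L] + 3L])
  a2 <- p[comp[2L] + 1L]; m2 <- p[comp[2L] + 2L]; s2 <- abs(p[comp[2L] + 3L])
  # a component collapsed to (near) zero amplitude is a one-Gaussian fit in
  # disguise: its D says nothing about bimodality
  d_stat <- if (min(a1, a2) < 0.5) NA_real_ else
    abs(m1 - m2) / sqrt((s1^2 + s2^2) / 2)
  structure(list(mean1 = m1, sd1 = s1, amp1 = a1,
                 mean2 = m2, sd2 = s2, amp2 = a2,
                 d_stat = d_stat, n_bins = n_bins, converged = TRUE),
            class = "bimodal_fit")
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat("<bimodal_fit>\n")
  if (!x$converged) {
    cat("  fit did not converge\n")
  } else {
    cat(sprintf("  G1: mean %.4g sd %.4g amp %.4g\n", x$mean1, x$sd1, x$amp1))
    cat(sprintf("  G2: mean %.4g sd %.4g amp %.4g\n", x$mean2, x$sd2, x$amp2))
    cat(sprintf("  Ashman\'s D = %.3f (%s)\n",
                x$d_stat,
                if (isTRUE(x$d_stat > 2)) "bimodal" else "not bimodal"))
  }
  invisible(x)
}

#' Objective detection thresholds from a bimodal fit
#' @param fit a converged `bimodal_fit` of the Metric3S histogram.
#' @return list with `seizure_thr` (`mean1 + 3*sd1`) and `lull_thr`
#'   (`mean1 - 3*sd1`).
#' @export
detection_thresholds <- function(fit) {
  check_bimodal(fit)
  list(seizure_thr = fit$mean1 + 3 * fit$sd1,
       lull_thr = fit$mean1 - 3 * fit$sd1)
}

check_bimodal <- function(fit) {
  stopifnot(inherits(fit, "bimodal_fit"))
  if (!isTRUE(fit$converged)) stop("bimodal fit did not converge")
  if (!is.finite(fit$d_stat) || fit$d_stat <= 2) {
    stop("distribution not bimodal (Ashman's D <= 2)")
  }
  invisible(fit)
}

# Window-run geometry: a 5 s window starting at integer second t overlaps a
# supra-threshold interval [a, b) iff t in (a - 5, b), so a run of flagged
# window starts {f..l} inverts to the interval [f + 4, l + 1) and a run of n
# windows means only n - 4 seconds of genuinely supra-threshold signal.
# This makes the < 5 s discard meaningful: an isolated hot second flags 5
# windows but implies a 1 s event, which is dropped.
flagged_runs_to_events <- function(flagged, window_starts, kind,
                                   min_duration_s = 0) {
  ev <- event_table()
  if (!any(flagged)) return(ev)
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts_i <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    t0 <- window_starts[starts_i[j]] + 4
    t1 <- window_starts[ends[j]] + 1
    if (t1 > t0 && (t1 - t0) >= min_duration_s) {
      ev <- rbind(ev, event_table(kind, t0, t1))
    }
  }
  rownames(ev) <- NULL
  ev
}

#' Detect electrographic seizures from a Metric3S series
#'
#' Windows whose metric value exceeds `mean1 + 3*sd1` of the leftmost
#' Gaussian are flagged; maximal contiguous runs of flagged windows are
#' inverted to the underlying supra-threshold interval
#' (`[first + 4, last + 1)` for 5 s windows stepped by 1 s), and events
#' shorter than 5 s are discarded.
#'
#' @param metric a `metric_series` from [metric3s()].
#' @param fit a converged `bimodal_fit` of `metric$values` with D > 2.
#' @param min_duration_s minimum seizure duration (default 5 s).
#' @return event data.frame (`kind`, `start`, `end`), possibly empty.
#' @export
detect_seizures <- function(metric, fit, min_duration_s = 5) {
  stopifnot(inherits(metric, "metric_series"))
  thr <- detection_thresholds(fit)$seizure_thr
  flagged <- metric$values > thr
  flagged_runs_to_events(flagged, metric$start_times, "seizure",
                         min_duration_s = min_duration_s)
}

#' Detect post-ictal lulls from a Metric3S series
#'
#' Windows whose metric value falls below `mean1 - 3*sd1` are flagged and
#' runs are inverted to events exactly as in [detect_seizures()], but with
#' no minimum duration (runs too short to imply a positive-length interval
#' still vanish).
#'
#' @inheritParams detect_seizures
#' @return event data.frame, possibly empty.
#' @export
detect_lulls <- function(metric, fit) {
  stopifnot(inherits(metric, "metric_series"))
  thr <- detection_thresholds(fit)$lull_thr
  flagged <- metric$values < thr
  flagged_runs_to_events(flagged, metric$start_times, "lull")
}

#' Detect inter-ictal spikes
#'
#' Slides a 30 ms window in 25 ms steps over the full-rate recording and
#' computes the max-min difference in each window.  The difference histogram
#' is fitted with two Gaussians (Ashman's D > 2 required) and windows whose
#' difference exceeds `mean2 + sd2` of the right-most Gaussian are flagged.
#' Overlapping/adjacent flagged windows are merged into one event, and
#' events intersecting a detected seizure are dropped.
#'
#' Windows overlapping a detected seizure, dilated by a `guard_s` peri-ictal
#' margin, are excluded from both the histogram fit and the flagging:
#' ictal spiking carries no inter-ictal information, detected offsets are
#' accurate only to a second or two so ictal activity can spill just past
#' the detected boundary, and at desk-scale record lengths those
#' large-amplitude windows would otherwise dominate the right-most Gaussian
#' and push the threshold above the true IIS mode.
#'
#' @param rec an [lfp_recording] at the original 2048 Hz rate.
#' @param seizures event data.frame of detected seizures (may be empty).
#' @param n_bins optional histogram bin count for [fit_bimodal()].
#' @param guard_s peri-ictal margin in seconds around each detected seizure
#'   (default 5) treated as ictal for IIS purposes.
#' @return event data.frame of IIS events.
#' @export
detect_iis <- function(rec, seizures = event_table(), n_bins = NULL,
                       guard_s = 5) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (abs(rec$fs - 2048) > 1e-6) {
    stop("IIS detection runs on the original 2048 Hz recording")
  }
  w <- round(0.030 * rec$fs)   # 61 samples
  step <- round(0.025 * rec$fs)  # 51 samples
  n <- length(rec$samples)
  if (n < w) stop("recording shorter than one IIS window")
  starts <- seq(1L, n - w + 1L, by = step)
  wmax <- rec$samples[starts]
  wmin <- wmax
  for (k in seq_len(w - 1L)) {
    v <- rec$samples[starts + k]
    wmax <- pmax(wmax, v)
    wmin <- pmin(wmin, v)
  }
  diffs <- wmax - wmin
  t_start <- rec$start_time + (starts - 1L) / rec$fs
  outside <- rep(TRUE, length(starts))
  if (nrow(seizures) > 0L) {
    for (i in seq_len(nrow(seizures))) {
      outside <- outside &
        !(t_start < seizures$end[i] + guard_s &
            (t_start + w / rec$fs) > seizures$start[i] - guard_s)
    }
  }
  fit <- fit_bimodal(diffs[outside], n_bins = n_bins)
  check_bimodal(fit)
  thr <- fit$mean2 + fit$sd2
  flagged <- diffs > thr & outside
  ev <- event_table()
  if (any(flagged)) {
    r <- rle(flagged)
    ends <- cumsum(r$lengths)
    starts_i <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      t0 <- rec$start_time + (starts[starts_i[j]] - 1L) / rec$fs
      t1 <- rec$start_time + (starts[ends[j]] - 1L + w) / rec$fs
      t1 <- min(t1, t0 + 0.999)  # IIS events are sub-second by definition
      ev <- rbind(ev, event_table("iis", t0, t1))
    }
  }
  if (nrow(ev) > 0L && nrow(seizures) > 0L) {
    keep <- vapply(seq_len(nrow(ev)), function(i) {
      !any(ev$start[i] < seizures$end & ev$end[i] > seizures$start)
    }, logical(1))
    ev <- ev[keep, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' One-call seizure/lull detection pipeline
#'
#' Downsamples to 256 Hz, computes the envelope, HV/LV, Metric3S, fits the
#' bimodal histogram and extracts seizure and lull events.
#'
#' A non-bimodal metric histogram (Ashman's D <= 2) means there is no
#' separable high-amplitude mode, i.e. no seizures: the wrapper then returns
#' empty event tables rather than raising the error the low-level detectors
#' use.
#'
#' @param rec an [lfp_recording] (any rate that is an integer multiple of
#'   256 Hz).
#' @param n_bins optional histogram bin count.
#' @return list with `seizures`, `lulls`, `metric` (the `metric_series`),
#'   `fit`, `thresholds` (NULL when not bimodal) and `bimodal` flag.
#' @export
detect_events <- function(rec, n_bins = NULL) {
  env <- hv_lv(epoch_minmax(downsample(rec, 256)))
  metric <- metric3s(env)
  fit <- fit_bimodal(metric$values, n_bins = n_bins)
  bimodal <- isTRUE(fit$converged) && is.finite(fit$d_stat) && fit$d_stat > 2
  if (!bimodal) {
    return(list(seizures = event_table(), lulls = event_table(),
                metric = metric, fit = fit, thresholds = NULL,
                bimodal = FALSE))
  }
  list(seizures = detect_seizures(metric, fit),
       lulls = detect_lulls(metric, fit),
       metric = metric, fit = fit,
       thresholds = detection_thresholds(fit), bimodal = TRUE)
}
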