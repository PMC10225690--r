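#' Configuration for the synthetic LFP generator
#'
#' Describes a simulated hippocampal LFP recording: a 1/f-shaped broadband
#' background with a small theta (8 Hz) component, a low-amplitude
#' high-frequency "hum" band (default 400-600 Hz, the band in which the
#' highest-frequency intrinsic mode of such recordings sits pre-ictally),
#' optional inter-ictal spikes (sharp biexponential transients, optionally
#' carrying 350-450 Hz pHFO ripples), electrographic seizures with large
#' rhythmic spiking and a programmed downward shift of the hum band, and a
#' low-amplitude post-ictal lull after every seizure.  The whole signal is
#' low-pass filtered at 600 Hz, emulating a recording chain with a broad
#' roll-off sampled at 2048 Hz.
#'
#' @param duration_s total duration in seconds.
#' @param fs sampling rate in Hz (>= 2048).
#' @param background_amp RMS amplitude of the 1/f background, mV.
#' @param hum_band length-2 numeric, low/high edge of the high-frequency
#'   band, Hz.
#' @param hum_amp RMS amplitude of the hum component, mV.
#' @param seizure_intervals list of `c(start, end)` pairs in seconds;
#'   must be disjoint and inside `[0, duration_s]`.
#' @param seizure_spike_rate rate of ictal rhythmic spikes, 1/s (2-10 is
#'   typical of electrographic seizures in this model).
#' @param seizure_amp_gain ictal amplitude gain (>= 1) applied to the hum and
#'   driving the ictal spike amplitude.
#' @param seizure_hum_ratio factor in (0, 1] by which the hum band is
#'   recentered during seizures (the programmed ictal frequency down-shift).
#' @param iis_times numeric vector of inter-ictal spike times, seconds.
#' @param iis_amp peak amplitude of inter-ictal spikes, mV.
#' @param iis_phfo_freq optional pHFO ripple frequency in `[350, 450]` Hz;
#'   when set, ripples ride on both inter-ictal and ictal spikes.
#' @param lull_duration_s duration of the post-ictal lull after each seizure.
#' @param lull_amp_gain amplitude gain in (0, 1) during lulls.
#' @param burst_rate rate of spindle-like 25 Hz oscillatory bursts in the
#'   background, 1/s.  These brief larger-amplitude transients give the
#'   amplitude-difference histograms of real LFP their second mode and are
#'   what the right-most Gaussian of the IIS detector latches onto;
#'   inter-ictal spikes stand clear above it.
#' @param burst_amp peak amplitude of the bursts, mV (default
#'   `2.5 * background_amp`).
#' @param seed integer RNG seed; the same seed gives a bit-identical record.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(duration_s,
                         fs = 2048,
                         background_amp = 0.05,
                         hum_band = c(400, 600),
                         hum_amp = 0.03,
                         seizure_intervals = list(),
                         seizure_spike_rate = 5,
                         seizure_amp_gain = 6,
                         seizure_hum_ratio = 0.64,
                         iis_times = numeric(),
                         iis_amp = 1,
                         iis_phfo_freq = NULL,
                         lull_duration_s = 10,
                         lull_amp_gain = 0.15,
                         burst_rate = 0.2,
                         burst_amp = NULL,
                         seed = 0L) {
  if (is.null(burst_amp)) burst_amp <- 2.5 * background_amp
  stopifnot(duration_s > 0, fs >= 2048,
            length(hum_band) == 2L, hum_band[1L] < hum_band[2L],
            background_amp >= 0, hum_amp >= 0,
            seizure_amp_gain >= 1,
            seizure_hum_ratio > 0, seizure_hum_ratio <= 1,
            lull_duration_s >= 0, lull_amp_gain > 0, lull_amp_gain < 1,
            iis_amp >= 0, burst_rate >= 0, burst_amp >= 0)
  if (!is.null(iis_phfo_freq)) {
    stopifnot(iis_phfo_freq >= 350, iis_phfo_freq <= 450)
  }
  if (is.matrix(seizure_intervals)) {
    seizure_intervals <- lapply(seq_len(nrow(seizure_intervals)),
                                function(i) seizure_intervals[i, ])
  }
  if (length(seizure_intervals) > 0L) {
    iv <- do.call(rbind, lapply(seizure_intervals, function(p) {
      stopifnot(length(p) == 2L, p[1L] < p[2L])
      as.numeric(p)
    }))
    iv <- iv[order(iv[, 1L]), , drop = FALSE]
    if (any(iv[, 1L] < 0) || any(iv[, 2L] > duration_s)) {
      stop("seizure intervals must lie inside [0, duration_s]")
    }
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
      stop("overlapping seizure intervals")
    }
    seizure_intervals <- lapply(seq_len(nrow(iv)), function(i) iv[i, ])
  }
  if (length(iis_times) > 0L) {
    stopifnot(all(iis_times >= 0), all(iis_times <= duration_s))
  }
  structure(
    list(duration_s = duration_s, fs = fs, background_amp = background_amp,
         hum_band = as.numeric(hum_band), hum_amp = hum_amp,
         seizure_intervals = seizure_intervals,
         seizure_spike_rate = seizure_spike_rate,
         seizure_amp_gain = seizure_amp_gain,
         seizure_hum_ratio = seizure_hum_ratio,
         iis_times = as.numeric(iis_times), iis_amp = iis_amp,
         iis_phfo_freq = iis_phfo_freq,
         lull_duration_s = lull_duration_s, lull_amp_gain = lull_amp_gain,
         burst_rate = burst_rate, burst_amp = burst_amp,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Build a synth_config from a flat key = value file
#' @param path configuration file (see [read_config()] for the syntax).
#' @return a `synth_config`.
#' @export
read_synth_config <- function(path) {
  vals <- read_config(path)
  known <- names(formals(synth_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$seizure_intervals) && is.numeric(vals$seizure_intervals)) {
    vals$seizure_intervals <- list(vals$seizure_intervals)
  }
  do.call(synth_config, vals)
}

# 1/f-amplitude-shaped Gaussian noise (spectral power exponent 1), flat
# below 1 Hz, zero-mean.  Built in the frequency domain so the shaping is
# exact and cheap even for hour-long records.
pink_noise <- function(n, fs) {
  white <- stats::rnorm(n)
  x <- stats::fft(white)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  scale <- 1 / sqrt(pmax(f, 1))
  scale[1L] <- 0
  Re(stats::fft(x * scale, inverse = TRUE)) / n
}

band_noise <- function(n, fs, band) {
  stopifnot(band[1L] > 0, band[2L] < fs / 2)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, stats::rnorm(n))
}

scale_rms <- function(x, target) {
  r <- sqrt(mean(x^2))
  if (r == 0 || target == 0) return(x * 0)
  x * (target / r)
}

# 0/1 mask over sample grid for a set of [start, end) intervals, with
# raised-cosine ramps of `ramp_s` seconds just inside each edge so that
# component switching does not itself inject broadband transients.
interval_mask <- function(n, fs, intervals, ramp_s = 0.25) {
  m <- numeric(n)
  for (iv in intervals) {
    i0 <- max(1L, round(iv[1L] * fs) + 1L)
    i1 <- min(n, round(iv[2L] * fs))
    if (i1 < i0) next
    seg <- rep(1, i1 - i0 + 1L)
    nr <- min(round(ramp_s * fs), floor(length(seg) / 2))
    if (nr > 0L) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
      seg[seq_len(nr)] <- ramp
      seg[length(seg) - nr + seq_len(nr)] <- rev(ramp)
    }
    m[i0:i1] <- pmax(m[i0:i1], seg)
  }
  m
}

#' Sharp biexponential spike waveform, optionally with a pHFO ripple
#'
#' The transient rises and decays with time constants tied to the requested
#' width so the waveform support is `round(width_ms/1000 * fs)` samples and
#' the peak is normalized to `amp`.  When `phfo_freq` is given, a
#' Gaussian-windowed sinusoid at that frequency (40% of the spike amplitude)
#' is superimposed around the spike peak, emulating pathological
#' high-frequency oscillations riding on epileptic spikes.
#'
#' @param width_ms waveform width in milliseconds (10-200).
#' @param amp peak amplitude, mV (>= 0; zero gives an all-zero waveform).
#' @param phfo_freq optional ripple frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return numeric vector of samples.
#' @export
make_iis_waveform <- function(width_ms, amp, phfo_freq = NULL, fs = 2048) {
  stopifnot(width_ms >= 10, width_ms <= 200)
  if (amp < 0) stop("spike amplitude must be non-negative")
  n <- round(width_ms / 1000 * fs)
  t <- (0:(n - 1)) / fs
  if (amp == 0) return(numeric(n))
  tw <- width_ms / 1000
  tau_r <- tw / 12
  tau_d <- tw / 4
  w <- exp(-t / tau_d) - exp(-t / tau_r)
  w <- w / max(w) * amp
  if (!is.null(phfo_freq)) {
    t_pk <- t[which.max(w)]
    env <- exp(-(t - t_pk)^2 / (2 * (tw / 8)^2))
    w <- w + 0.4 * amp * env * sin(2 * pi * phfo_freq * (t - t_pk))
  }
  w
}

add_transient <- function(sig, wave, at_sample) {
  i0 <- at_sample
  i1 <- min(length(sig), i0 + length(wave) - 1L)
  if (i0 < 1L || i0 > length(sig)) return(sig)
  sig[i0:i1] <- sig[i0:i1] + wave[seq_len(i1 - i0 + 1L)]
  sig
}

#' Generate a synthetic LFP recording with ground truth
#'
#' Produces a seeded, bit-reproducible simulated recording following the
#' structure described in [synth_config()], together with a ground-truth
#' event log (seizures, the post-ictal lull after each, and inter-ictal
#' spikes) and the programmed pre-ictal and ictal hum center frequencies.
#'
#' @param config a [synth_config].
#' @return a list with elements `recording` (an [lfp_recording]) and `truth`
#'   (list with `events` data.frame and `hum_center_pre`, `hum_center_ictal`).
#' @examples
#' out <- generate_recording(synth_config(30, seed = 1))
#' out$recording
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  n <- round(config$duration_s * fs)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  tt <- (0:(n - 1)) / fs
  bg <- scale_rms(pink_noise(n, fs), config$background_amp)
  theta <- 0.5 * config$background_amp * sin(2 * pi * 8 * tt + stats::runif(1, 0, 2 * pi))

  # spindle/beta-like 25 Hz bursts (0.4 s, flat-topped Tukey envelope so the
  # burst's full swing is visible in any 30 ms window), exponential gaps
  if (config$burst_rate > 0 && config$burst_amp > 0) {
    n_b <- round(0.4 * fs)
    i_b <- seq_len(n_b)
    nr <- round(0.2 * n_b)
    burst_env <- rep(1, n_b)
    burst_env[i_b <= nr] <- 0.5 * (1 - cos(pi * i_b[i_b <= nr] / nr))
    burst_env[i_b > n_b - nr] <- rev(burst_env[i_b <= nr])
    t_b <- stats::rexp(1, config$burst_rate)
    while (t_b < config$duration_s - 0.4) {
      ph <- stats::runif(1, 0, 2 * pi)
      wb <- config$burst_amp * burst_env *
        sin(2 * pi * 25 * (i_b / fs) + ph)
      bg <- add_transient(bg, wb, round(t_b * fs) + 1L)
      t_b <- t_b + 0.4 + stats::rexp(1, config$burst_rate)
    }
  }

  hum <- scale_rms(band_noise(n, fs, config$hum_band), config$hum_amp)
  has_sz <- length(config$seizure_intervals) > 0L
  ict_mask <- if (has_sz) {
    interval_mask(n, fs, config$seizure_intervals)
  } else numeric(n)
  lull_iv <- lapply(config$seizure_intervals, function(iv) {
    c(iv[2L], min(iv[2L] + config$lull_duration_s, config$duration_s))
  })
  lull_mask <- if (has_sz && config$lull_duration_s > 0) {
    interval_mask(n, fs, lull_iv)
  } else numeric(n)
  amp_env <- 1 - (1 - config$lull_amp_gain) * lull_mask

  if (has_sz && config$hum_amp > 0) {
    hum_ict <- scale_rms(band_noise(n, fs, config$hum_band * config$seizure_hum_ratio),
                         config$hum_amp)
    hum_all <- hum * (1 - ict_mask) * amp_env +
      hum_ict * ict_mask * config$seizure_amp_gain
  } else {
    hum_all <- hum * amp_env
  }

  sig <- (bg + theta) * amp_env + hum_all

  # ictal rhythmic spiking; the train wanes ~1.5 s before offset as real
  # electrographic seizures do
  spike_amp0 <- 2 * config$background_amp * config$seizure_amp_gain
  for (iv in config$seizure_intervals) {
    t_sp <- iv[1L] + 0.3
    while (t_sp < iv[2L] - 1.5) {
      amp <- spike_amp0 * stats::runif(1, 0.85, 1.15)
      if (amp > 0) {
        w <- make_iis_waveform(60, amp, phfo_freq = config$iis_phfo_freq, fs = fs)
        sig <- add_transient(sig, -w, round(t_sp * fs) + 1L)
      }
      t_sp <- t_sp + stats::runif(1, 0.9, 1.1) / config$seizure_spike_rate
    }
  }

  # inter-ictal spikes with the classic spike-and-wave morphology: sharp
  # biexponential spike followed by a slower 100 ms after-wave at 80% of
  # the spike amplitude
  iis_events <- event_table()
  for (t_sp in config$iis_times) {
    width <- stats::runif(1, 30, 80)
    amp <- config$iis_amp * stats::runif(1, 0.95, 1.05)
    if (amp > 0) {
      w <- make_iis_waveform(width, amp, phfo_freq = config$iis_phfo_freq, fs = fs)
      n_wave <- round(0.100 * fs)
      wave <- 0.8 * amp * sin(pi * seq_len(n_wave) / n_wave)
      i0 <- round(t_sp * fs) + 1L
      sig <- add_transient(sig, -w, i0)
      sig <- add_transient(sig, -wave, i0 + which.max(w))
    }
    iis_events <- rbind(iis_events,
                        event_table("iis", t_sp, min(t_sp + width / 1000,
                                                     config$duration_s)))
  }

  # amplifier-like low-pass at 600 Hz (zero-phase so event timing is exact)
  if (any(sig != 0)) {
    lp <- signal::butter(4, 600 / (fs / 2), type = "low")
    sig <- signal::filtfilt(lp, sig)
  }

  events <- iis_events
  for (iv in config$seizure_intervals) {
    events <- rbind(events, event_table("seizure", iv[1L], iv[2L]))
  }
  for (iv in lull_iv) {
    events <- rbind(events, event_table("lull", iv[1L], iv[2L]))
  }
  events <- events[order(events$start, events$kind), , drop = FALSE]
  rownames(events) <- NULL

  list(
    recording = lfp_recording(sig, fs = fs,
                              label = sprintf("synthetic seed=%d", config$seed)),
    truth = list(
      events = events,
      hum_center_pre = mean(config$hum_band),
      hum_center_ictal = mean(config$hum_band) * config$seizure_hum_ratio
    )
  )
}
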