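# small signal builders shared across the suite

make_tone <- function(freq, dur_s = 1, fs = 2048, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(dur_s * fs) - 1)) / fs + phase)
}

tone_recording <- function(freq, dur_s = 1, fs = 2048, amp = 1) {
  lfp_recording(make_tone(freq, dur_s, fs, amp), fs = fs)
}

# envelope_series built directly (bypassing a recording) for metric tests
fake_env <- function(max_wave, min_wave, start_time = 0) {
  env <- structure(
    list(max_wave = max_wave, min_wave = min_wave, hv = NULL, lv = NULL,
         epoch_s = 0.125, start_time = start_time),
    class = "envelope_series")
  env
}

# a metric series with chosen values at integer start seconds
fake_metric <- function(values, start_times = seq_along(values) - 1) {
  structure(list(values = values, start_times = start_times,
                 window_s = 5, step_s = 1),
            class = "metric_series")
}

# a bimodal fit object with chosen parameters (for threshold-rule tests)
fake_fit <- function(mean1, sd1, mean2, sd2, amp1 = 100, amp2 = 10) {
  structure(list(mean1 = mean1, sd1 = sd1, amp1 = amp1,
                 mean2 = mean2, sd2 = sd2, amp2 = amp2,
                 d_stat = abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2),
                 n_bins = 50L, converged = TRUE),
            class = "bimodal_fit")
}

# per-phase feature frame as epoch_features() would produce it
fake_features <- function(epoch_start, imf_index, center_freq, spectral_rms,
                          phase_start = min(epoch_start), n_epochs = length(unique(epoch_start))) {
  f <- data.frame(epoch_start = epoch_start, imf_index = imf_index,
                  center_freq = center_freq, spectral_rms = spectral_rms)
  attr(f, "phase_start") <- phase_start
  attr(f, "n_epochs") <- n_epochs
  f
}
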