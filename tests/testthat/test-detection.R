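test_that("downsampling preserves the passband and kills aliases", {
  rec <- tone_recording(10, dur_s = 8, fs = 2048)
  ds <- downsample(rec, 256)
  expect_equal(ds$fs, 256)
  expect_equal(length(ds$samples), 2048L)

  spec_amp <- function(x, fs, f) {
    n <- length(x)
    2 * Mod(stats::fft(x))[round(f * n / fs) + 1L] / n
  }
  expect_equal(spec_amp(ds$samples, 256, 10), 1, tolerance = 0.01)

  rec300 <- tone_recording(300, dur_s = 8, fs = 2048)
  ds300 <- downsample(rec300, 256)
  # 300 Hz aliases to 44 Hz at 256 Hz sampling; anti-alias filter removes it
  alias_power <- spec_amp(ds300$samples, 256, 44)^2
  expect_lt(alias_power, 0.01)

  expect_error(downsample(tone_recording(10, fs = 2048), 300), "integer multiple")
})

test_that("125 ms epoching takes exact 32-sample extremes", {
  rec <- lfp_recording(rep(2.5, 256 * 10), fs = 256)
  env <- epoch_minmax(rec)
  expect_equal(length(env$max_wave), 80L)
  expect_true(all(env$max_wave == 2.5) && all(env$min_wave == 2.5))

  saw <- lfp_recording(rep(seq(-1, 1, length.out = 32), 16), fs = 256)
  env2 <- epoch_minmax(saw)
  expect_true(all(env2$max_wave == 1) && all(env2$min_wave == -1))

  # trailing partial epoch dropped
  env3 <- epoch_minmax(lfp_recording(numeric(32 * 4 + 10), fs = 256))
  expect_equal(length(env3$max_wave), 4L)

  expect_error(epoch_minmax(lfp_recording(numeric(10), fs = 256)), "shorter")
  expect_error(epoch_minmax(lfp_recording(numeric(64), fs = 2048)), "256 Hz")
})

test_that("HV/LV follow the printed forward-looking formulas exactly", {
  env <- fake_env(max_wave = c(11, 1, 1), min_wave = c(10, 0, 0))
  env <- hv_lv(env)
  expect_equal(env$hv, 1)   # min(11, max(1, 1))
  expect_equal(env$lv, 10)  # max(10, min(0, 0)); HV - LV may be negative

  env2 <- hv_lv(fake_env(c(3, 2, 1), c(0, 0, 0)))
  expect_equal(env2$hv, 2)
  expect_equal(env2$lv, 0)

  env3 <- hv_lv(fake_env(rep(4, 10), rep(4, 10)))
  expect_true(all(env3$hv == 4) && all(env3$lv == 4))
  expect_equal(length(env3$hv), 8L)

  expect_error(hv_lv(fake_env(c(1, 2), c(0, 0))), "3 epochs")

  # brute-force re-evaluation on random envelopes
  set.seed(99)
  for (rep in 1:5) {
    mx <- rnorm(50)
    mn <- mx - abs(rnorm(50))
    env_r <- hv_lv(fake_env(mx, mn))
    hv_ref <- sapply(1:48, function(i) min(mx[i], max(mx[i + 1], mx[i + 2])))
    lv_ref <- sapply(1:48, function(i) max(mn[i], min(mn[i + 1], mn[i + 2])))
    expect_identical(env_r$hv, hv_ref)
    expect_identical(env_r$lv, lv_ref)
  }
})

test_that("Metric3S sums 40 epochs per 5 s window stepped by 1 s", {
  # 12.25 s of epochs: every full window has all 40 HV terms available
  n_ep <- 98L
  env <- fake_env(rep(1, n_ep), rep(0, n_ep))
  env <- hv_lv(env)
  m <- metric3s(env)
  expect_true(all(m$values == 40))

  # 12 s record: windows start at 0..7 s
  env2 <- hv_lv(fake_env(rep(1, 96), rep(0, 96)))
  m2 <- metric3s(env2)
  expect_equal(length(m2$values), 8L)
  expect_equal(m2$start_times, 0:7)

  # constant signal gives all-zero metric
  env3 <- hv_lv(fake_env(rep(2, 60), rep(2, 60)))
  expect_true(all(metric3s(env3)$values == 0))

  # equality with naive summation on random envelopes
  set.seed(7)
  mx <- rnorm(120); mn <- mx - abs(rnorm(120))
  env4 <- hv_lv(fake_env(mx, mn))
  m4 <- metric3s(env4)
  d <- env4$hv - env4$lv
  naive <- sapply(m4$start_times, function(t) {
    idx <- (t * 8 + 1):min((t + 5) * 8, length(d))
    sum(d[idx])
  })
  expect_equal(m4$values, naive, tolerance = 1e-12)

  expect_error(metric3s(hv_lv(fake_env(rep(1, 30), rep(0, 30)))), "5 s")
})

test_that("Ashman's D separates mixtures and rejects unimodal samples", {
  set.seed(11)
  f <- fit_bimodal(c(rnorm(2500, 0), rnorm(2500, 8)))
  expect_true(f$converged)
  expect_lt(abs(f$d_stat - 8) / 8, 0.15)
  expect_lt(abs(f$mean1 - 0), 0.3)
  expect_lt(abs(f$mean2 - 8), 0.3)

  set.seed(12)
  f0 <- fit_bimodal(rnorm(5000))
  expect_lt(f0$d_stat, 2)

  fc <- fit_bimodal(rep(1, 200))
  expect_false(fc$converged)

  expect_error(fit_bimodal(rnorm(50)), "100 values")
  expect_error(fit_bimodal(rnorm(200), n_bins = 10), "20")
})

test_that("flagged window runs invert to the supra-threshold interval", {
  # background 5, elevated interval [20, 40): windows 16..39 flag
  vals <- rep(5, 96)
  for (t in 0:95) {
    ov <- max(0, min(t + 5, 40) - max(t, 20))
    vals[t + 1] <- 5 + ov * 4
  }
  m <- fake_metric(vals, 0:95)
  fit <- fake_fit(5, 0.5, 60, 10)
  ev <- detect_seizures(m, fit)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 20)
  expect_equal(ev$end, 40)

  # a single hot second flags 5 windows but implies a 1 s event: discarded
  vals2 <- rep(5, 60)
  vals2[26:30] <- 30  # windows 25..29 (covering hot second 29.5) flag
  ev2 <- detect_seizures(fake_metric(vals2, 0:59), fit)
  expect_equal(nrow(ev2), 0L)

  # nothing above threshold
  expect_equal(nrow(detect_seizures(fake_metric(rep(5, 60), 0:59), fit)), 0L)

  # non-bimodal fit is refused
  expect_error(detect_seizures(m, fake_fit(5, 2, 7, 2)), "not bimodal")
})

test_that("lull detection mirrors seizure detection below the left mode", {
  vals <- rep(5, 60)
  vals[21:28] <- 0.5   # windows 20..27 flag low -> interval [24, 28)
  fit <- fake_fit(5, 0.5, 60, 10)
  ev <- detect_lulls(fake_metric(vals, 0:59), fit)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start, 24)
  expect_equal(ev$end, 28)
  expect_equal(nrow(detect_lulls(fake_metric(rep(5, 60), 0:59), fit)), 0L)
})

test_that("programmed seizures and lulls are recovered end to end", {
  for (s in c(3, 8)) {
    dur <- 10 * (s %/% 3)
    cfg <- synth_config(300 + dur,
                        seizure_intervals = list(c(140, 140 + dur)), seed = s)
    out <- generate_recording(cfg)
    det <- detect_events(out$recording)
    expect_true(det$bimodal)
    expect_equal(nrow(det$seizures), 1L)
    expect_lt(abs(det$seizures$start - 140), 3)
    expect_lt(abs(det$seizures$end - (140 + dur)), 3)
    expect_gte(det$seizures$end - det$seizures$start, 5)

    truth_lull <- c(140 + dur, 140 + dur + cfg$lull_duration_s)
    ov <- min(det$lulls$end[1], truth_lull[2]) - max(det$lulls$start[1], truth_lull[1])
    expect_gte(ov / diff(truth_lull), 0.5)
  }
})

test_that("IIS detection flags out-of-seizure spikes and honors exclusions", {
  cfg <- synth_config(200, seizure_intervals = list(c(80, 100)),
                      iis_times = c(20, 35, 50, 65, 85, 90, 150), seed = 11)
  out <- generate_recording(cfg)
  det <- detect_events(out$recording)
  iis <- detect_iis(out$recording, det$seizures)
  expect_equal(nrow(iis), 5L)
  for (t in c(20, 35, 50, 65, 150)) {
    expect_true(any(iis$start <= t + 0.2 & iis$end >= t - 0.2))
  }
  expect_false(any(iis$start > 75 & iis$end < 105))
  expect_true(all(iis$end - iis$start < 1))

  # constant signal: degenerate unimodal histogram
  expect_error(detect_iis(lfp_recording(rep(1, 2048 * 60), fs = 2048)),
               "not bimodal|converge")
  # wrong rate
  expect_error(detect_iis(lfp_recording(numeric(256 * 60), fs = 256)), "2048")
})

test_that("adjacent flagged IIS windows merge into one event", {
  # one isolated spike-and-wave on a quiet-but-structured background
  cfg <- synth_config(120, iis_times = seq(10, 110, by = 10), seed = 4)
  out <- generate_recording(cfg)
  iis <- detect_iis(out$recording)
  # events must be disjoint: no two events within one window length
  if (nrow(iis) > 1) {
    expect_true(all(diff(iis$start) > 0.03))
    expect_true(all(iis$start[-1] >= iis$end[-nrow(iis)]))
  }
  expect_gte(nrow(iis), 1L)
})

test_that("a seizure-free record yields no events", {
  out <- generate_recording(synth_config(360, seed = 4))
  det <- detect_events(out$recording)
  expect_false(det$bimodal)
  expect_equal(nrow(det$seizures), 0L)
  expect_equal(nrow(det$lulls), 0L)
})
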