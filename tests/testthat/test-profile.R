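test_that("the analysis triplet spans three equal seizure durations", {
  rec <- lfp_recording(numeric(400 * 2048) + 1, fs = 2048)
  tri <- extract_triplet(rec, data.frame(start = 100, end = 120))
  expect_equal(tri$pre$start_time, 80)
  expect_equal(rec_duration(tri$pre), 20)
  expect_equal(tri$ictal$start_time, 100)
  expect_equal(tri$post$start_time, 120)
  expect_equal(rec_duration(tri$pre) + rec_duration(tri$ictal) +
                 rec_duration(tri$post), 60)

  expect_error(extract_triplet(rec, data.frame(start = 5, end = 25)), "pre")
  expect_error(extract_triplet(rec, data.frame(start = 370, end = 390)), "post")
})

test_that("per-second features recover tone frequencies per epoch", {
  phase <- tone_recording(400, dur_s = 5, fs = 2048)
  f <- epoch_features(phase)
  f1 <- f[f$imf_index == 1, ]
  expect_equal(nrow(f1), 5L)
  expect_true(all(abs(f1$center_freq - 400) <= 2))

  fz <- epoch_features(lfp_recording(numeric(2 * 2048), fs = 2048))
  expect_equal(nrow(fz), 0L)

  # 20 1-s epochs from a 20.6 s phase (trailing partial dropped)
  out <- generate_recording(synth_config(21, seed = 3))
  f20 <- epoch_features(rec_window(out$recording, 0, 20.6))
  expect_equal(length(unique(f20$epoch_start)), 20L)
})

test_that("quintile aggregation averages epochs into 15 relative-time points", {
  mk <- function(start, n, rms) {
    fake_features(start + 0:(n - 1), rep(1L, n),
                  center_freq = rep(500, n), spectral_rms = rms,
                  phase_start = start)
  }
  pre <- mk(0, 10, rep(1, 10))
  ict <- mk(10, 10, 1:10)
  post <- mk(20, 10, rep(2, 10))
  prof <- quintile_aggregate(pre, ict, post, 10)
  expect_equal(nrow(prof), 15L)
  expect_equal(prof$relative_time_index, 1:15)
  sz <- prof[prof$relative_time_index %in% 6:10, ]
  expect_equal(sz$mean_rms, c(1.5, 3.5, 5.5, 7.5, 9.5))
  expect_true(all(prof$n_epochs[6:10] == 2))

  # 7 s phase: midpoints 0.5..6.5 against quintile bins of width 1.4
  ict7 <- mk(10, 7, rep(1, 7))
  prof7 <- quintile_aggregate(mk(3, 7, rep(1, 7)), ict7, mk(17, 7, rep(1, 7)), 7)
  occ <- prof7$n_epochs[prof7$relative_time_index %in% 6:10]
  expect_equal(occ, c(1, 2, 1, 2, 1))

  expect_error(quintile_aggregate(pre, ict, post, 4), "5 s")
})

test_that("quintile means do not depend on epoch order within a bin", {
  mk2 <- function(ord) {
    fake_features(c(10, 11, 12, 13, 14, 15, 16, 17, 18, 19)[ord],
                  rep(1L, 10), center_freq = (101:110)[ord],
                  spectral_rms = (1:10)[ord], phase_start = 10)
  }
  base <- mk2(1:10)
  shuf <- mk2(c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  p1 <- quintile_aggregate(base, base, base, 10)
  p2 <- quintile_aggregate(shuf, shuf, shuf, 10)
  expect_equal(p1$mean_center_freq, p2$mean_center_freq)
  expect_equal(p1$mean_rms, p2$mean_rms)
})

test_that("the seizure comparison picks the max-RMS quintile", {
  mk <- function(start, rms5) {
    fake_features(start + 0:9, rep(1L, 10), center_freq = rep(450, 10),
                  spectral_rms = rep(rms5, each = 2), phase_start = start)
  }
  pre <- mk(0, rep(2, 5))
  ict <- mk(10, c(1, 9, 3, 2, 1))
  post <- mk(20, rep(2, 5))
  prof <- quintile_aggregate(pre, ict, post, 10)
  cmp <- compare_seizure(prof, pre, imf_index = 1L)
  expect_equal(cmp$max_rms_quintile, 2L)
  expect_equal(cmp$max_rms, 9)
  expect_equal(cmp$pre_mean_rms, 2)
  expect_equal(cmp$pre_mean_freq, 450)

  expect_error(compare_seizure(prof, pre, imf_index = 4L), "IMF 4")
})

test_that("a stationary record yields a flat IMF1 quintile profile", {
  out <- generate_recording(synth_config(31, seed = 41))
  sz <- data.frame(start = 10.5, end = 20.5)
  tri <- extract_triplet(out$recording, sz)
  feats <- lapply(tri, epoch_features)
  prof <- quintile_aggregate(feats$pre, feats$ictal, feats$post, 10)
  f1 <- prof[prof$imf_index == 1, ]
  expect_equal(nrow(f1), 15L)
  expect_lt(max(abs(f1$mean_center_freq - mean(f1$mean_center_freq))) /
              mean(f1$mean_center_freq), 0.05)

  cmp <- compare_seizure(prof, feats$pre, 1L)
  expect_lt(abs(cmp$freq_at_max_rms_quintile / cmp$pre_mean_freq - 1), 0.05)
})

test_that("the programmed ictal frequency drop is recovered for IMF1", {
  cfg <- synth_config(100, seizure_intervals = list(c(40, 60)), seed = 1)
  out <- generate_recording(cfg)
  res <- analyze_seizure(out$recording, data.frame(start = 40, end = 60))
  cmp <- res$comparison
  ratio <- cmp$freq_at_max_rms_quintile / cmp$pre_mean_freq
  expect_gte(ratio, 0.54)
  expect_lte(ratio, 0.74)
  expect_gte(cmp$pre_mean_freq, 400)   # pre-ictal IMF1 sits in the hum band
  expect_lte(cmp$pre_mean_freq, 600)
  expect_gt(cmp$max_rms, 10 * cmp$pre_mean_rms)  # ictal power surge

  # profile drops during seizure quintiles and recovers after
  f1 <- res$profile[res$profile$imf_index == 1, ]
  pre_mean <- mean(f1$mean_center_freq[f1$relative_time_index %in% 1:5])
  sz_mean <- mean(f1$mean_center_freq[f1$relative_time_index %in% 7:9])
  post_tail <- mean(f1$mean_center_freq[f1$relative_time_index %in% 12:15])
  expect_lt(sz_mean, 0.8 * pre_mean)
  expect_gt(post_tail, 0.9 * pre_mean)
})
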