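test_that("extrema and zero crossings are counted with plateau handling", {
  # 2 full periods, 100 samples each; phase offset avoids exact-zero samples
  x <- make_tone(2, dur_s = 1, fs = 200, phase = 0.1)
  ex <- find_extrema(x)
  expect_equal(length(ex$maxima), 2L)
  expect_equal(length(ex$minima), 2L)
  expect_equal(ex$n_zero_crossings, 4L)

  # exact zeros inherit the previous sign: a touch is not a crossing
  expect_equal(find_extrema(c(1, 0, 1, -1, 0, -1, 1))$n_zero_crossings, 2L)

  expect_equal(length(find_extrema(1:100)$maxima), 0L)
  expect_equal(length(find_extrema(1:100)$minima), 0L)

  ex_p <- find_extrema(c(0, 1, 1, 0))
  expect_equal(ex_p$maxima, 2L)  # plateau counted once at its midpoint
  expect_equal(length(ex_p$minima), 0L)

  ex_0 <- find_extrema(rep(3, 10))
  expect_equal(length(ex_0$maxima) + length(ex_0$minima), 0L)
  expect_equal(ex_0$n_zero_crossings, 0L)
})

test_that("the mean spline envelope is flat for symmetric oscillations", {
  x <- make_tone(8, dur_s = 1, fs = 512)
  m <- envelope_mean(x)
  interior <- 52:460  # central 80%
  expect_lt(max(abs(m[interior])), 0.01)

  m_c <- envelope_mean(x + 3)
  expect_lt(max(abs(m_c[interior] - 3)), 0.03)

  one_max <- c(seq(0, 1, length.out = 50), seq(1, 0, length.out = 50))
  expect_error(envelope_mean(one_max), "monotone|few extrema")
})

test_that("sifting recovers single modes and separates distant tones", {
  tone <- make_tone(32, dur_s = 1, fs = 2048)
  s <- sift(tone)
  expect_gte(cor(s$imf, tone), 0.99)
  expect_lte(s$n_iter, 2 + 2)  # already an IMF: stops within s_number + 2

  slow <- make_tone(4, dur_s = 1, fs = 2048)
  fast <- make_tone(64, dur_s = 1, fs = 2048)
  d <- decompose_emd(slow + fast, fs = 2048)
  expect_gte(cor(d$imfs[[1]], fast), 0.95)
})

test_that("decomposition terminates on monotone input and reconstructs", {
  ramp <- seq(0, 1, length.out = 256)
  d <- decompose_emd(ramp, fs = 256)
  expect_equal(length(d$imfs), 0L)
  expect_equal(d$residual, ramp)

  tone <- make_tone(32, dur_s = 1, fs = 2048)
  d2 <- decompose_emd(tone + seq(0, 2, length.out = 2048), fs = 2048)
  expect_gte(cor(d2$imfs[[1]], tone), 0.95)
  recon2 <- Reduce(`+`, d2$imfs) + d2$residual
  expect_lt(max(abs(recon2 - (tone + seq(0, 2, length.out = 2048)))),
            1e-8 * 4)
})

test_that("reconstruction identity and IMF conditions hold on random signals", {
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(1024)
    d <- decompose_emd(x, fs = 1024)
    recon <- Reduce(`+`, d$imfs) + d$residual
    expect_lt(max(abs(recon - x)), 1e-8 * diff(range(x)))
    expect_true(all(vapply(d$imfs, is_imf, logical(1))))
    expect_lte(length(d$imfs), 12L)
  }
})

test_that("is_imf applies both printed conditions", {
  tone <- make_tone(32, dur_s = 1, fs = 2048)
  expect_true(is_imf(tone))
  expect_false(is_imf(tone + 5))           # envelope mean ~ offset
  expect_false(is_imf(seq(0, 1, length.out = 100)))  # no oscillation
  expect_false(is_imf(numeric(100)))
})

test_that("synthetic LFP epochs decompose into the expected IMF ladder depth", {
  out <- generate_recording(synth_config(7, seed = 9))
  d <- decompose_emd(out$recording$samples, fs = 2048)
  expect_gte(length(d$imfs), 7L)
  expect_lte(length(d$imfs), 12L)
})

test_that("decomposition agrees with an independent sifting implementation", {
  oracle <- system.file("oracle", "emd_sift.py", package = "lfpemd")
  expect_true(nzchar(oracle))
  in_csv <- withr::local_tempfile(fileext = ".csv")
  out_csv <- withr::local_tempfile(fileext = ".csv")

  n_checked <- 0
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(512)
    d <- decompose_emd(x, fs = 512)
    utils::write.table(x, in_csv, row.names = FALSE, col.names = FALSE)
    status <- system2("python", c(oracle, in_csv, out_csv),
                      stdout = FALSE, stderr = FALSE)
    expect_equal(status, 0L)
    ref <- as.matrix(utils::read.csv(out_csv, header = FALSE))
    n_ref_imfs <- ncol(ref) - 1L
    for (k in seq_len(min(3L, length(d$imfs), n_ref_imfs))) {
      # greedy match: best-correlated oracle IMF for each of ours
      cors <- vapply(seq_len(n_ref_imfs),
                     function(j) abs(cor(d$imfs[[k]], ref[, j])), numeric(1))
      expect_gte(max(cors), 0.9)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 20)
})
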