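#' One-sided magnitude-squared spectrum of an IMF
#'
#' Plain DFT magnitude squared, DC bin retained, no zero padding, so a 1 s
#' epoch at 2048 Hz yields a 1 Hz frequency grid.  All downstream spectral
#' quantities (rectangle fit, centroid, spectral RMS) work on this
#' representation.
#'
#' @param imf numeric vector, length >= 64.
#' @param fs sampling rate in Hz.
#' @param source_imf_index optional IMF index carried for bookkeeping.
#' @return an `imf_spectrum`: list with `freqs` (Hz, starting at 0, step
#'   `fs/N`), `power` (mV^2), `fs`, `n`, `source_imf_index`.
#' @export
imf_spectrum <- function(imf, fs, source_imf_index = NA_integer_) {
  imf <- as.numeric(imf)
  n <- length(imf)
  stopifnot(n >= 64L)
  half <- floor(n / 2)
  x <- stats::fft(imf)
  structure(
    list(freqs = (0:half) * fs / n,
         power = Mod(x[1:(half + 1L)])^2,
         fs = fs, n = n,
         source_imf_index = as.integer(source_imf_index)),
    class = "imf_spectrum"
  )
}

spectrum_area <- function(spec) {
  df <- spec$freqs[2L] - spec$freqs[1L]
  sum(spec$power) * df
}

#' Equivalent-rectangle fit of an IMF spectrum
#'
#' Finds the rectangle whose area equals the total spectrum area and whose
#' overlap in area with the spectrum is maximal.  Candidate rectangles span
#' inclusive bin ranges `[f_lo, f_hi]` on the frequency grid; for a range of
#' `w` bins the height is `A / (w * df)` (equal area) and the overlap is the
#' shared area `sum(pmin(power, height)) * df` over the range.  All bin
#' ranges are searched; ties are broken toward the narrower rectangle, then
#' toward the lower `f_lo`.  The rectangle center is the IMF's center
#' frequency; the edges are its minimum and maximum frequencies.
#'
#' @param spec an [imf_spectrum()].
#' @return a `rectangle_fit`: list with `f_lo`, `f_hi`, `height`,
#'   `center_freq`, `overlap_area`.
#' @export
rectangle_fit <- function(spec) {
  stopifnot(inherits(spec, "imf_spectrum"))
  p <- spec$power
  n <- length(p)
  df <- spec$freqs[2L] - spec$freqs[1L]
  a <- sum(p) * df
  if (a <= 0) stop("zero-area spectrum")
  cs_best <- -Inf
  best <- c(NA_integer_, NA_integer_)
  for (w in 2:n) {
    h <- a / (w * df)
    cm <- c(0, cumsum(pmin(p, h)))
    ov <- (cm[(w + 1L):(n + 1L)] - cm[1:(n - w + 1L)]) * df
    i <- which.max(ov)
    if (ov[i] > cs_best) {
      cs_best <- ov[i]
      best <- c(i, i + w - 1L)
    }
  }
  f_lo <- spec$freqs[best[1L]]
  f_hi <- spec$freqs[best[2L]]
  w <- best[2L] - best[1L] + 1L
  structure(
    list(f_lo = f_lo, f_hi = f_hi, height = a / (w * df),
         center_freq = (f_lo + f_hi) / 2, overlap_area = cs_best),
    class = "rectangle_fit"
  )
}

#' Spectrum centroid (center of gravity) by the integral method
#'
#' Treats the region under the power curve as a planar lamina: the abscissa
#' of its center of gravity is the centroid frequency,
#' `sum(f * P) / sum(P)`, and the ordinate, `sum(P^2 / 2) / sum(P)`, is the
#' magnitude-squared value of the centroid (h/2 for a rectangle of height
#' h).  Integrals are bin sums on the uniform frequency grid.
#'
#' @param spec an [imf_spectrum()].
#' @return a `centroid_fit`: list with `centroid_freq`, `centroid_power`.
#' @export
centroid_fit <- function(spec) {
  stopifnot(inherits(spec, "imf_spectrum"))
  p <- spec$power
  tot <- sum(p)
  if (tot <= 0) stop("zero-area spectrum")
  structure(
    list(centroid_freq = sum(spec$freqs * p) / tot,
         centroid_power = sum(p^2 / 2) / tot),
    class = "centroid_fit"
  )
}

#' Spectral RMS of an IMF
#'
#' Root mean square of the one-sided magnitude-squared spectrum values,
#' used as the spectral power of the IMF (units mV^2: quadratic in signal
#' amplitude).
#'
#' @param spec an [imf_spectrum()].
#' @return a single number.
#' @export
spectral_rms <- function(spec) {
  stopifnot(inherits(spec, "imf_spectrum"))
  sqrt(mean(spec$power^2))
}

#' Full spectral summary of one IMF
#' @param imf numeric vector.
#' @param fs sampling rate, Hz.
#' @param source_imf_index IMF index for bookkeeping.
#' @return list with `rect`, `centroid`, `spectral_rms`.
#' @export
spectral_summary <- function(imf, fs, source_imf_index = NA_integer_) {
  spec <- imf_spectrum(imf, fs, source_imf_index)
  list(rect = rectangle_fit(spec),
       centroid = centroid_fit(spec),
       spectral_rms = spectral_rms(spec))
}

#' Per-IMF spectral ladder of a decomposition
#'
#' Summarizes every IMF of an [decompose_emd()] result (rectangle center and
#' edges, centroid, spectral RMS) and fits the least-squares slope of
#' `log(center_freq)` against IMF index.  Successive IMFs of broadband
#' signals behave like a dyadic filter bank, so the slope is negative and
#' close to `-log(2)`.  All-zero IMFs are skipped with a warning.
#'
#' @param imfset an `imf_set`.
#' @return list with `summaries` (data.frame: `imf_index`, `center_freq`,
#'   `f_lo`, `f_hi`, `height`, `centroid_freq`, `centroid_power`,
#'   `spectral_rms`) and `log_slope`.
#' @export
frequency_ladder <- function(imfset) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imfset$imfs) == 0L) stop("decomposition contains no IMFs")
  rows <- list()
  for (i in seq_along(imfset$imfs)) {
    imf <- imfset$imfs[[i]]
    if (all(imf == 0)) {
      warning(sprintf("IMF %d has zero power; skipped", i))
      next
    }
    s <- spectral_summary(imf, imfset$fs, i)
    rows[[length(rows) + 1L]] <- data.frame(
      imf_index = i,
      center_freq = s$rect$center_freq,
      f_lo = s$rect$f_lo, f_hi = s$rect$f_hi, height = s$rect$height,
      centroid_freq = s$centroid$centroid_freq,
      centroid_power = s$centroid$centroid_power,
      spectral_rms = s$spectral_rms)
  }
  summaries <- do.call(rbind, rows)
  log_slope <- NA_real_
  pos <- summaries$center_freq > 0
  if (sum(pos) >= 2L) {
    log_slope <- unname(stats::coef(stats::lm(
      log(center_freq) ~ imf_index, data = summaries[pos, ]))[2L])
  }
  list(summaries = summaries, log_slope = log_slope)
}
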