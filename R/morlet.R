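#' Morlet continuous wavelet transform of a recording
#'
#' Complex Morlet CWT on a linear frequency grid (default 100-700 Hz in
#' 1 Hz steps, w0 = 6), computed per frequency by FFT convolution with the
#' analytic Morlet kernel.  The scale for frequency f uses the standard
#' Morlet center-frequency relation `s = (w0 + sqrt(2 + w0^2)) / (4*pi*f)`.
#' The magnitude matrix is Z-scored over the entire time-frequency plane
#' ([zscore_matrix()]) so pHFO episodes stand out as high-Z islands.
#'
#' @param rec an [lfp_recording].
#' @param fmin,fmax frequency range in Hz; `fmax` must stay below 70% of
#'   Nyquist so the wavelet kernels are well sampled.
#' @param df frequency step in Hz.
#' @param w0 Morlet time-frequency trade-off parameter.
#' @return a `wavelet_matrix`: list with `times` (s), `freqs` (Hz),
#'   `magnitude` and `zscore` (freq x time matrices), `w0`.
#' @export
morlet_cwt <- function(rec, fmin = 100, fmax = 700, df = 1, w0 = 6) {
  stopifnot(inherits(rec, "lfp_recording"), fmin > 0, fmax > fmin, df > 0)
  if (fmax >= 0.7 * rec$fs / 2) {
    stop("fmax must be below 0.7 * Nyquist for a well-sampled Morlet kernel")
  }
  x <- rec$samples
  n <- length(x)
  dt <- 1 / rec$fs
  n2 <- 2^ceiling(log2(n))     # zero-pad to limit wraparound
  xh <- stats::fft(c(x, numeric(n2 - n)))
  k <- 0:(n2 - 1L)
  omega <- 2 * pi * ifelse(k <= n2 / 2, k, k - n2) / (n2 * dt)
  freqs <- seq(fmin, fmax, by = df)
  fourier_factor <- (w0 + sqrt(2 + w0^2)) / (4 * pi)
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  norm0 <- pi^(-1 / 4)
  pos <- omega > 0
  for (i in seq_along(freqs)) {
    s <- fourier_factor / freqs[i]
    psi_hat <- numeric(n2)
    psi_hat[pos] <- norm0 * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[pos] - w0)^2 / 2)
    w <- stats::fft(xh * psi_hat, inverse = TRUE) / n2
    mag[i, ] <- Mod(w[1:n])
  }
  structure(
    list(times = rec$start_time + (0:(n - 1L)) * dt,
         freqs = freqs, magnitude = mag,
         zscore = zscore_matrix(mag), w0 = w0),
    class = "wavelet_matrix"
  )
}

#' Z-score a time-frequency matrix over its entire extent
#'
#' Subtracts the global mean and divides by the global SD of all cells, so
#' the map shows relative changes in magnitude; display clipping (e.g. to
#' a 0-10 color scale) is left to plotting code.
#'
#' @param magnitude numeric matrix with positive SD.
#' @return matrix of the same shape with global mean 0 and SD 1.
#' @export
zscore_matrix <- function(magnitude) {
  stopifnot(is.matrix(magnitude))
  mu <- mean(magnitude)
  sdv <- stats::sd(as.vector(magnitude))
  if (!is.finite(sdv) || sdv == 0) stop("degenerate matrix: zero variance")
  (magnitude - mu) / sdv
}

#' @export
print.wavelet_matrix <- function(x, ...) {
  cat(sprintf("<wavelet_matrix> %d freqs (%g-%g Hz) x %d times, w0 = %g\n",
              length(x$freqs), min(x$freqs), max(x$freqs),
              length(x$times), x$w0))
  invisible(x)
}

#' Heatmap of a Z-scored wavelet matrix
#'
#' Base-graphics image of the Z-score map, clipped to `[0, zmax]` as is
#' conventional for pHFO displays.
#'
#' @param x a `wavelet_matrix`.
#' @param zmax upper clip of the Z color scale (default 10).
#' @param ... passed to [graphics::image()].
#' @export
plot.wavelet_matrix <- function(x, zmax = 10, ...) {
  z <- pmin(pmax(x$zscore, 0), zmax)
  graphics::image(x$times, x$freqs, t(z),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  zlim = c(0, zmax), ...)
  invisible(x)
}
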