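# exhaustive O(n^2) reference for the equal-area rectangle search
rectangle_oracle <- function(spec) {
  p <- spec$power
  n <- length(p)
  df <- spec$freqs[2] - spec$freqs[1]
  a <- sum(p) * df
  best_ov <- -Inf
  best <- c(NA, NA)
  for (w in 2:n) {
    h <- a / (w * df)
    for (lo in 1:(n - w + 1)) {
      ov <- sum(pmin(p[lo:(lo + w - 1)], h)) * df
      if (ov > best_ov) {
        best_ov <- ov
        best <- c(lo, lo + w - 1)
      }
    }
  }
  list(f_lo = spec$freqs[best[1]], f_hi = spec$freqs[best[2]],
       overlap = best_ov)
}

fake_spectrum <- function(power, df = 1, fs = NULL) {
  n <- length(power)
  structure(list(freqs = (0:(n - 1)) * df, power = power,
                 fs = if (is.null(fs)) 2 * n * df else fs,
                 n = 2L * n, source_imf_index = NA_integer_),
            class = "imf_spectrum")
}
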