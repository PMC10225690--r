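#' Sifting configuration for empirical mode decomposition
#'
#' @param s_number S-number stopping criterion: sifting stops after
#'   `s_number` consecutive iterations in which the numbers of extrema and
#'   zero crossings are unchanged and differ by at most one (default 2).
#' @param max_sift_iter hard cap on sifting iterations per IMF.
#' @param max_imfs maximum number of IMFs to extract.
#' @param boundary extremum boundary rule; only `"mirror"` (reflection of
#'   the two outermost extrema about each end) is implemented.
#' @return a `sift_config`.
#' @export
sift_config <- function(s_number = 2L, max_sift_iter = 100L, max_imfs = 12L,
                        boundary = "mirror") {
  stopifnot(s_number >= 1L, max_sift_iter >= 1L, max_imfs >= 1L)
  boundary <- match.arg(boundary, "mirror")
  structure(list(s_number = as.integer(s_number),
                 max_sift_iter = as.integer(max_sift_iter),
                 max_imfs = as.integer(max_imfs),
                 boundary = boundary),
            class = "sift_config")
}

#' Locate strict local extrema and count zero crossings
#'
#' Plateaus of equal values count as a single extremum at the plateau
#' midpoint.  Zero crossings are sign changes of the sequence; exact zeros
#' inherit the preceding sign so a touch without a crossing is not counted.
#'
#' @param x numeric vector, length >= 3.
#' @return list with integer vectors `maxima` and `minima` (indices) and
#'   `n_zero_crossings`.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  stopifnot(n >= 3L)
  r <- rle(x)
  k <- length(r$values)
  maxima <- integer(0)
  minima <- integer(0)
  if (k >= 3L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    v <- r$values
    j <- 2:(k - 1L)
    is_max <- v[j] > v[j - 1L] & v[j] > v[j + 1L]
    is_min <- v[j] < v[j - 1L] & v[j] < v[j + 1L]
    mid <- (starts[j] + ends[j]) %/% 2L
    maxima <- mid[is_max]
    minima <- mid[is_min]
  }
  # zeros inherit the previous sign, so crossings are the sign changes among
  # successive non-zero samples (leading zeros carry no sign)
  s <- sign(x)
  s <- s[s != 0]
  n_zc <- if (length(s) >= 2L) sum(diff(s) != 0) else 0L
  list(maxima = maxima, minima = minima, n_zero_crossings = as.integer(n_zc))
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' Natural cubic splines are fitted through the local maxima (upper
#' envelope) and minima (lower envelope), each end mirror-extended by two
#' extrema to tame boundary swings, and the pointwise mean of the two
#' envelopes is returned.  This is the quantity subtracted at each sifting
#' step.
#'
#' @param x numeric vector with at least 2 maxima and 2 minima.
#' @return numeric vector, same length as `x`.
#' @export
envelope_mean <- function(x) {
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
    stop("monotone residual: too few extrema for envelopes")
  }
  n <- length(x)
  upper <- spline_envelope(ex$maxima, x[ex$maxima], n)
  lower <- spline_envelope(ex$minima, x[ex$minima], n)
  (upper + lower) / 2
}

spline_envelope <- function(idx, val, n) {
  m <- length(idx)
  e <- min(2L, m)
  left_t <- 2 - idx[seq_len(e)]        # reflect about position 1
  left_v <- val[seq_len(e)]
  right_t <- 2L * n - idx[m - seq_len(e) + 1L]  # reflect about position n
  right_v <- val[m - seq_len(e) + 1L]
  tt <- c(rev(left_t), idx, rev(right_t))
  vv <- c(rev(left_v), val, rev(right_v))
  keep <- !duplicated(tt)
  stats::spline(tt[keep], vv[keep], xout = seq_len(n), method = "natural")$y
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates `h <- h - envelope_mean(h)` and stops by the S-number rule: once
#' the extremum and zero-crossing counts have stayed identical for
#' `s_number` consecutive iterations while differing by at most one, or at
#' `max_sift_iter`.
#'
#' @param x numeric vector with at least 2 maxima and 2 minima.
#' @param cfg a [sift_config()].
#' @return list with `imf` (numeric vector) and `n_iter` (iterations used).
#' @export
sift <- function(x, cfg = sift_config()) {
  h <- x
  streak <- 0L
  prev <- NULL
  n_iter <- 0L
  best <- NULL
  for (it in seq_len(cfg$max_sift_iter)) {
    m <- tryCatch(envelope_mean(h), error = function(e) NULL)
    if (is.null(m)) break
    qualifies <- (!is.null(prev) && abs(prev[1L] - prev[2L]) <= 1L) &&
      max(abs(m)) <= 0.05 * max(abs(h))
    # remember the latest iterate satisfying both IMF conditions; if the
    # iteration cap fires mid-oscillation (mode mixing can make the counts
    # flip indefinitely) that qualifying snapshot is returned instead
    if (qualifies) best <- h
    # stop once counts have been stable for s_number iterations AND the
    # candidate already satisfies the near-zero envelope-mean condition
    if (streak >= cfg$s_number && max(abs(m)) <= 0.05 * max(abs(h))) break
    h <- h - m
    n_iter <- it
    ex <- find_extrema(h)
    ne <- length(ex$maxima) + length(ex$minima)
    nz <- ex$n_zero_crossings
    ok <- abs(ne - nz) <= 1L &&
      !is.null(prev) && ne == prev[1L] && nz == prev[2L]
    streak <- if (ok) streak + 1L else 0L
    prev <- c(ne, nz)
  }
  if (n_iter >= cfg$max_sift_iter && !is.null(best)) h <- best
  list(imf = h, n_iter = n_iter)
}

#' Empirical mode decomposition
#'
#' Repeatedly sifts the running residual, peeling off IMFs from the fastest
#' local oscillation downwards, until the residual has fewer than 3 extrema
#' (or too few for envelopes) or `max_imfs` have been extracted.  By
#' construction the IMFs and residual sum back to the input exactly up to
#' floating-point round-off.
#'
#' @param x numeric vector, length >= 64.
#' @param fs sampling rate in Hz (carried along for spectral analysis).
#' @param cfg a [sift_config()].
#' @return an `imf_set`: list with `imfs` (list of numeric vectors, imf 1 =
#'   highest frequency), `residual`, `source_len`, `fs`.
#' @examples
#' x <- sin(2 * pi * 4 * (0:2047) / 2048) + sin(2 * pi * 64 * (0:2047) / 2048)
#' d <- decompose_emd(x, fs = 2048)
#' length(d$imfs)
#' @export
decompose_emd <- function(x, fs, cfg = sift_config()) {
  x <- as.numeric(x)
  stopifnot(length(x) >= 64L)
  imfs <- list()
  resid <- x
  while (length(imfs) < cfg$max_imfs) {
    ex <- find_extrema(resid)
    if (length(ex$maxima) + length(ex$minima) < 3L ||
        length(ex$maxima) < 2L || length(ex$minima) < 2L) break
    s <- sift(resid, cfg)
    if (all(s$imf == 0)) break
    # a component too sparse to support envelopes (fewer than 2 maxima or
    # 2 minima) cannot satisfy the IMF definition; leave it in the residual
    ex_i <- find_extrema(s$imf)
    if (length(ex_i$maxima) < 2L || length(ex_i$minima) < 2L) break
    imfs[[length(imfs) + 1L]] <- s$imf
    resid <- resid - s$imf
  }
  structure(list(imfs = imfs, residual = resid,
                 source_len = length(x), fs = fs),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residual (%d samples @ %g Hz)\n",
              length(x$imfs), x$source_len, x$fs))
  invisible(x)
}

#' Test the two defining IMF conditions
#'
#' True iff (1) the numbers of extrema and zero crossings differ by at most
#' one and (2) the mean envelope is everywhere small:
#' `max |envelope_mean(x)| <= tol * max |x|`.  The envelope tolerance
#' (default 5% of the peak) replaces the theoretical exact zero, which is
#' unattainable numerically.
#'
#' @param x numeric vector, length >= 3.
#' @param tol relative envelope-mean tolerance.
#' @return logical flag.
#' @export
is_imf <- function(x, tol = 0.05) {
  if (length(x) < 3L || all(x == 0)) return(FALSE)
  ex <- find_extrema(x)
  ne <- length(ex$maxima) + length(ex$minima)
  if (abs(ne - ex$n_zero_crossings) > 1L) return(FALSE)
  m <- tryCatch(envelope_mean(x), error = function(e) NULL)
  if (is.null(m)) return(FALSE)
  max(abs(m)) <= tol * max(abs(x))
}
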