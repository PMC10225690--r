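#' Cut the pre-seizure / seizure / post-seizure triplet
#'
#' The analysis window around a seizure is three times the seizure duration:
#' an equal-duration pre-seizure phase immediately before onset, the seizure
#' itself, and an equal-duration post-seizure phase immediately after offset.
#'
#' @param rec an [lfp_recording] covering `[start - d, end + d]` where `d`
#'   is the seizure duration.
#' @param seizure one-row event data.frame (or list) with `start`, `end`.
#' @return list of three [lfp_recording]s: `pre`, `ictal`, `post`.
#' @export
extract_triplet <- function(rec, seizure) {
  stopifnot(inherits(rec, "lfp_recording"))
  s0 <- seizure$start[1L]
  s1 <- seizure$end[1L]
  d <- s1 - s0
  stopifnot(d > 0)
  t0 <- rec$start_time
  t1 <- rec$start_time + rec_duration(rec)
  if (s0 - d < t0 - 1e-9) stop("insufficient pre-seizure context in recording")
  if (s1 + d > t1 + 1e-9) stop("insufficient post-seizure context in recording")
  list(pre = rec_window(rec, s0 - d, s0),
       ictal = rec_window(rec, s0, s1),
       post = rec_window(rec, s1, s1 + d))
}

#' Per-second spectral features of a phase
#'
#' Decomposes each non-overlapping 1 s epoch of the phase by EMD and
#' records, for every IMF, the rectangle center frequency and spectral RMS.
#' Epochs with no decomposable structure (e.g. an all-zero signal) yield no
#' rows.  A trailing partial second is dropped.
#'
#' @param phase an [lfp_recording] of at least 1 s.
#' @param cfg a [sift_config()].
#' @return data.frame with columns `epoch_start` (absolute, s), `imf_index`,
#'   `center_freq` (Hz), `spectral_rms` (mV^2); attribute `phase_start`
#'   holds the phase's start time and `n_epochs` the epoch count.
#' @export
epoch_features <- function(phase, cfg = sift_config()) {
  stopifnot(inherits(phase, "lfp_recording"))
  n_ep <- floor(rec_duration(phase) + 1e-9)
  if (n_ep < 1L) stop("phase must be at least 1 s long")
  spp <- as.integer(round(phase$fs))
  rows <- list()
  for (e in seq_len(n_ep)) {
    x <- phase$samples[((e - 1L) * spp + 1L):(e * spp)]
    t_ep <- phase$start_time + (e - 1L)
    if (all(x == 0)) next
    dec <- decompose_emd(x, phase$fs, cfg)
    if (length(dec$imfs) == 0L) next
    lad <- suppressWarnings(frequency_ladder(dec))
    s <- lad$summaries
    rows[[length(rows) + 1L]] <- data.frame(
      epoch_start = t_ep, imf_index = s$imf_index,
      center_freq = s$center_freq, spectral_rms = s$spectral_rms)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(epoch_start = numeric(), imf_index = integer(),
               center_freq = numeric(), spectral_rms = numeric())
  attr(out, "phase_start") <- phase$start_time
  attr(out, "n_epochs") <- n_ep
  out
}

# an epoch belongs to the quintile bin [k*d/5, (k+1)*d/5) containing its
# midpoint; midpoints at or past the last edge stay in bin 5
quintile_of <- function(midpoint, d) {
  pmin(5L, as.integer(floor(midpoint / (d / 5))) + 1L)
}

#' Quintile-normalized 15-point profile
#'
#' Each of the three phases (pre, seizure, post, all of duration `d`) is
#' divided into 5 equal relative-time quintiles; every 1 s epoch is assigned
#' to the quintile containing its midpoint, and per-quintile
#' arithmetic means of center frequency and spectral RMS are formed for each
#' IMF.  The result is 15 equidistant relative-time points per IMF
#' (1-5 pre, 6-10 seizure, 11-15 post), making seizures of different
#' durations comparable.
#'
#' @param pre,ictal,post `epoch_features()` frames for the three phases.
#' @param seizure_duration the common phase duration `d` in seconds.
#' @return a `quintile_profile`: data.frame with `imf_index`,
#'   `relative_time_index` (1-15), `phase`, `mean_center_freq`, `mean_rms`,
#'   `n_epochs`.
#' @export
quintile_aggregate <- function(pre, ictal, post, seizure_duration) {
  d <- seizure_duration
  if (d < 5) stop("phases shorter than 5 s cannot be split into quintiles")
  phases <- list(pre = pre, ictal = ictal, post = post)
  offs <- c(pre = 0L, ictal = 5L, post = 10L)
  pieces <- list()
  for (ph in names(phases)) {
    f <- phases[[ph]]
    if (nrow(f) == 0L) next
    p0 <- attr(f, "phase_start")
    if (is.null(p0)) p0 <- min(f$epoch_start)
    mid <- f$epoch_start - p0 + 0.5
    q <- quintile_of(mid, d)
    fq <- data.frame(f, q = q)
    agg <- stats::aggregate(cbind(center_freq, spectral_rms) ~ imf_index + q,
                            data = fq, FUN = mean)
    cnt <- stats::aggregate(epoch_start ~ imf_index + q, data = fq,
                            FUN = length)
    pieces[[ph]] <- data.frame(
      imf_index = agg$imf_index,
      relative_time_index = agg$q + offs[[ph]],
      phase = if (ph == "ictal") "seizure" else ph,
      mean_center_freq = agg$center_freq,
      mean_rms = agg$spectral_rms,
      n_epochs = cnt$epoch_start)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$imf_index, out$relative_time_index), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("quintile_profile", "data.frame")
  out
}

#' Pre-seizure vs seizure comparison for one IMF
#'
#' Identifies the seizure quintile with the largest mean spectral RMS and
#' pairs its mean center frequency with the average center frequency of the
#' same IMF over all pre-seizure epochs (the paired quantities whose ratio
#' captures the ictal frequency shift).
#'
#' @param profile a [quintile_aggregate()] result.
#' @param pre_features `epoch_features()` frame of the pre-seizure phase.
#' @param imf_index which IMF to compare (default 1, the fastest).
#' @param min_presence minimum fraction of pre epochs in which the IMF must
#'   be present (default 0.8).
#' @return a `seizure_comparison`: list with `imf_index`, `pre_mean_freq`,
#'   `freq_at_max_rms_quintile`, `pre_mean_rms`, `max_rms`,
#'   `max_rms_quintile`.
#' @export
compare_seizure <- function(profile, pre_features, imf_index = 1L,
                            min_presence = 0.8) {
  stopifnot(inherits(profile, "quintile_profile"))
  n_ep <- attr(pre_features, "n_epochs")
  if (is.null(n_ep)) n_ep <- length(unique(pre_features$epoch_start))
  pre_i <- pre_features[pre_features$imf_index == imf_index, , drop = FALSE]
  if (nrow(pre_i) < min_presence * n_ep) {
    stop(sprintf("IMF %d present in too few pre-seizure epochs", imf_index))
  }
  sz <- profile[profile$imf_index == imf_index &
                  profile$relative_time_index %in% 6:10, , drop = FALSE]
  if (nrow(sz) == 0L) stop(sprintf("IMF %d absent from seizure quintiles", imf_index))
  k <- which.max(sz$mean_rms)
  structure(
    list(imf_index = as.integer(imf_index),
         pre_mean_freq = mean(pre_i$center_freq),
         freq_at_max_rms_quintile = sz$mean_center_freq[k],
         pre_mean_rms = mean(pre_i$spectral_rms),
         max_rms = sz$mean_rms[k],
         max_rms_quintile = as.integer(sz$relative_time_index[k] - 5L)),
    class = "seizure_comparison"
  )
}

#' @export
print.seizure_comparison <- function(x, ...) {
  cat(sprintf("<seizure_comparison> IMF%d\n", x$imf_index))
  cat(sprintf("  pre-seizure mean center frequency : %8.1f Hz\n", x$pre_mean_freq))
  cat(sprintf("  frequency at max-RMS quintile (#%d): %8.1f Hz  (ratio %.2f)\n",
              x$max_rms_quintile, x$freq_at_max_rms_quintile,
              x$freq_at_max_rms_quintile / x$pre_mean_freq))
  cat(sprintf("  pre-seizure mean spectral RMS     : %8.3g mV^2\n", x$pre_mean_rms))
  cat(sprintf("  max seizure-quintile spectral RMS : %8.3g mV^2\n", x$max_rms))
  invisible(x)
}

#' End-to-end quintile analysis of one seizure
#'
#' Cuts the equal-duration pre/ictal/post triplet, computes per-second EMD
#' spectral features for each phase, aggregates them into the 15-point
#' quintile profile and extracts the pre-vs-ictal comparison for one IMF.
#'
#' @param rec an [lfp_recording] with enough context around the seizure.
#' @param seizure one-row event data.frame with `start`, `end`.
#' @param imf_index IMF to compare (default 1).
#' @param cfg a [sift_config()].
#' @return list with `profile`, `comparison`, `features` (named list of the
#'   three per-phase feature frames).
#' @export
analyze_seizure <- function(rec, seizure, imf_index = 1L, cfg = sift_config()) {
  tri <- extract_triplet(rec, seizure)
  feats <- lapply(tri, epoch_features, cfg = cfg)
  d <- seizure$end[1L] - seizure$start[1L]
  prof <- quintile_aggregate(feats$pre, feats$ictal, feats$post, d)
  cmp <- compare_seizure(prof, feats$pre, imf_index = imf_index)
  list(profile = prof, comparison = cmp, features = feats)
}
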