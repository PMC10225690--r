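---
title: "Methods: EMD-based spectral profiling of epileptic LFP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMD-based spectral profiling of epileptic LFP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lfpemd)
```

# Overview

`lfpemd` analyzes chronic single-channel local field potential (LFP)
recordings from epileptic tissue (amplitudes in mV, sampled at 2048 Hz and
low-pass filtered at 600 Hz by a recording chain with a broad roll-off).
The pipeline has four stages:

1. **Event detection** — electrographic seizures and post-ictal lulls from
   an amplitude-range metric with objective bimodal-histogram thresholds;
   inter-ictal spikes (IIS) from a sliding max–min difference signal.
2. **Empirical mode decomposition (EMD)** — sifting with the S-number
   stopping criterion splits each epoch into intrinsic mode functions
   (IMFs), ordered from the fastest local oscillation (IMF1) downwards.
3. **Spectral characterization** — each IMF's magnitude-squared FFT
   spectrum is summarized by an equivalent-rectangle center frequency,
   a planar centroid, and a spectral RMS power.
4. **Quintile profiling and statistics** — per-second features around each
   seizure are normalized to 15 relative-time points (5 per phase:
   pre-ictal, ictal, post-ictal) so seizures of different durations can be
   averaged and compared; the accompanying statistics are farthest-point
   clustering, regression through the origin, and the Wilcoxon paired
   signed-rank test.

The scientific signal of interest is the fast end of the spectrum: the
center frequency of IMF1 sits in a 400–600 Hz band between seizures (a
"desynchronized hum"), drops by roughly a third during seizures generated
near the recording site, recovers quickly afterwards, and co-occurs with
pathological high-frequency oscillations (pHFOs, 350–450 Hz) riding on
epileptic spikes.  Z-scored Morlet wavelet maps (100–700 Hz, 1 Hz steps,
`w0 = 6`) visualize the pHFOs.

# Seizure, lull and IIS detection

The detector down-samples to 256 Hz (zero-phase Butterworth anti-alias
filter at `0.4 * 256` Hz, order 8, then decimation), splits the signal into
125 ms epochs of exactly 32 samples, and records per-epoch extremes
(`Max_wave`, `Min_wave`).  Forward-looking order statistics suppress
single-epoch transients:

```
HV[i] = min(max_wave[i], max(max_wave[i+1], max_wave[i+2]))
LV[i] = max(min_wave[i], min(min_wave[i+1], min_wave[i+2]))
```

`Metric3S` sums `HV - LV` over the 40 epochs of a 5 s window stepped by
1 s.  Its all-point histogram is modelled as two normal components; the
bimodality index (Ashman's D)

```
D = |mean1 - mean2| / sqrt((sd1^2 + sd2^2) / 2)
```

must exceed 2 before thresholds are applied: seizures above
`mean1 + 3*sd1`, lulls below `mean1 - 3*sd1` of the left-most (background)
Gaussian.  Detected seizures shorter than 5 s are discarded.

## Numerical choices in the histogram model

Several details of the two-component model are implementation-defined and
were chosen for robustness on heavily imbalanced mixtures (a few dozen
seizure windows among hours of background):

* **Split point.** The components are separated at the dominant mode's
  robust tail, `median + 8 * MAD`, whenever at least `max(5, 0.2%)` of the
  values lie beyond it; otherwise at the boundary of a deterministic
  2-means partition seeded from the data extremes.  On unimodal data the
  fallback produces two strongly overlapping components and `D` stays well
  below 2, so the detectors refuse to threshold.
* **Component estimation.** The components play different roles and are
  estimated accordingly.  The background component must describe the
  histogram *core* — its `mean1 ± 3*sd1` sets the event thresholds — so it
  is a least-squares Gaussian fit to the histogram counts (Levenberg–
  Marquardt), which a few percent of contaminating windows (lulls, partial
  event overlap) cannot distort.  The right-most component must describe
  the *entire* event cluster — `mean2 + sd2` is the IIS threshold and has
  to clear the cluster's low sub-populations (spike after-waves, partially
  overlapping windows) — so it is the moment (maximum-likelihood) normal of
  the values on that side.  A component whose fitted amplitude falls below
  one count is treated as collapsed and the fit as non-bimodal.
* **Binning.** Freedman–Diaconis, clamped to 50–100 bins: an extreme but
  rare second mode stretches the range, and unclamped FD would dilute it
  into empty bins.

## Event boundaries from flagged windows

A 5 s window starting at integer second `t` overlaps a supra-threshold
interval `[a, b)` exactly when `t` lies in `(a - 5, b)`.  A maximal run of
flagged window starts `{f, ..., l}` is therefore inverted to the event
`[f + 4, l + 1)`, and a run of `n` windows implies only `n - 4` s of
genuinely supra-threshold signal — the duration to which the < 5 s discard
is applied.  This geometric inversion keeps onset/offset errors within a
second or two and makes the discard rule meaningful: an isolated hot second
flags five windows but implies a 1 s event, which is dropped.  (Attributing
each window's value to a single second, as one might naively do, biases
onsets by up to the window length and makes every detection at least 5 s
long.)

## IIS detection

IIS are detected on the original 2048 Hz signal from the max–min difference
of a 30 ms window sliding in 25 ms steps (61 samples, step 51).  The
difference histogram is modelled as above; windows whose difference exceeds
`mean2 + sd2` of the right-most component are flagged, adjacent flagged
windows merge into one event, and events intersecting detected seizures
are ignored.  Two pipeline-level choices:

* Windows inside detected seizures, dilated by a 5 s peri-ictal guard band,
  are excluded *before* the histogram fit.  Ictal spiking carries no
  inter-ictal information, detected offsets are only accurate to a second
  or two, and on desk-scale records the ictal windows would otherwise
  dominate the right-most component and push the threshold above the IIS
  mode.  (On 12 h recordings the ictal fraction is negligible and this
  makes no difference.)
* The `mean2 + sd2` rule detects spikes only because the right-most mode is
  *bottom-heavy*: its mass comes from spike after-waves, partial-overlap
  windows and background amplitude transients, with the spike-peak windows
  at its top.  The threshold then lands between the two, and every spike
  contributes at least one peak-covering window (the 25 ms step is smaller
  than the 30 ms window).  Sensitivity on synthetic records is high but not
  guaranteed to be 100% for arbitrary noise draws; false detections are
  essentially absent because nothing else reaches the flagged range.

# Empirical mode decomposition

Sifting iterates `h <- h - envelope_mean(h)`, where the mean envelope is
the average of natural cubic splines through the local maxima and minima.
An IMF must satisfy (1) extrema and zero-crossing counts equal or differing
by at most one, and (2) a locally zero mean envelope.  Stopping follows the
S-number criterion with `S = 2`: the counts must be stable (unchanged, and
differing by at most one) for S consecutive iterations.  Decomposition
peels IMFs off the running residual until it has fewer than three extrema
or 12 IMFs have been extracted; by construction the IMFs and residual sum
back to the input to floating-point precision.

Implementation-defined details:

* **Boundary rule**: the two outermost extrema at each end are mirrored
  about the first/last sample before spline fitting, the standard remedy
  for end swings.  Plateaus count as a single extremum at their midpoint;
  exact zeros inherit the preceding sign (a touch is not a crossing).
* **Envelope tolerance**: condition (2) is enforced as
  `max |envelope_mean| <= 5%` of the peak amplitude — exact zero is
  unattainable numerically.
* **Stopping**: the S-number rule alone can leave a visible envelope bias
  (~7% of peak) in occasional IMFs, so sifting additionally requires the
  5% envelope condition before stopping.  If the 100-iteration cap fires
  while the counts oscillate (mode mixing), the most recent iterate that
  satisfied both IMF conditions is returned.
* Mode mixing is not corrected (no ensemble variants); IMFs are aligned
  across epochs positionally (IMF1 with IMF1, and so on).

On broadband input EMD behaves like a dyadic filter bank: successive IMF
center frequencies halve, which shows as a log-linear ladder (median
successive ratio ~2).  For the synthetic LFP the package estimates this
ratio pooled over the 1 s epochs of several 7 s records, because a single
epoch contributes only ~9 adjacent pairs and its median is noisy.

# Spectral characterization of IMFs

Spectra are plain one-sided DFT magnitude-squared values with the DC bin
retained and no zero padding, so 1 s epochs at 2048 Hz give a 1 Hz grid.
Three summaries per IMF:

* **Equivalent rectangle.** Among all rectangles spanning inclusive bin
  ranges `[f_lo, f_hi]` with area equal to the spectrum's total area
  (height `A / width`), the fit maximizes the shared area
  `sum(pmin(power, height)) * df` over the range; ties prefer the narrower
  rectangle, then the lower `f_lo`.  The rectangle's center is the IMF's
  center frequency; its edges are the minimum and maximum frequencies.
  The search enumerates every bin width (overlap is evaluated for all
  offsets of a width in one vectorized pass, so the full search is
  exhaustive yet costs only ~25 ms on a 1025-bin spectrum) and is tested
  for exact agreement against an independent brute-force oracle.
  Integrals use bin sums (`sum(p) * df`) rather than trapezoids so that a
  bin-aligned rectangular spectrum is recovered exactly.
* **Centroid.** The region under the power curve is treated as a planar
  lamina: centroid frequency `sum(f*P)/sum(P)` and centroid ordinate
  `sum(P^2/2)/sum(P)` (h/2 for a rectangle of height h, matching the
  power-like quantity plotted in published ladders).
* **Spectral RMS** — `sqrt(mean(power^2))`, units mV², quadratic in signal
  amplitude; used as the IMF's spectral power.

# Quintile profiling

The analysis window around a detected seizure is three times its duration:
equal-length pre-ictal and post-ictal phases flank the seizure.  Every
non-overlapping 1 s epoch is decomposed and per-IMF center frequencies and
spectral RMS recorded.  Each phase is divided into five equal relative-time
quintiles; an epoch belongs to the quintile containing its midpoint.
Per-quintile means give 15 relative-time points per IMF.  For the headline
comparison, the seizure quintile with the largest mean RMS is selected and
its mean center frequency is paired with the average over *all* pre-ictal
epochs (not pre-ictal quintiles).  The pre-ictal/ictal frequency pairs of
several seizures are then clustered (farthest-point, k = 2, first center
the point farthest from the data mean) to set aside seizures whose fast
component never slows — volume-conducted events — and a line through the
origin is fitted to the rest; a slope below 1, with a 95% CI excluding 1,
quantifies the proportional ictal frequency drop.

# The synthetic data generator

No recordings are distributed with the package, so validation runs on a
seeded generator that emulates the statistical structure the analysis
assumes, with a ground-truth event log.  Components (defaults in
parentheses; all chosen once, before the test suite was frozen):

* 1/f-shaped Gaussian background (RMS 0.05 mV, spectrum flattened below
  1 Hz) plus a small 8 Hz theta sinusoid — this broadband base is what
  yields the 8–12 IMF ladder.
* Spindle-like 25 Hz bursts (0.4 s, flat-topped envelope, peak amplitude
  2.5× background RMS, rate 0.2/s).  Real LFP has such amplitude
  transients; they give the IIS difference histogram its genuine second
  mode.
* A band-limited high-frequency "hum" (400–600 Hz, RMS 0.03 mV), the
  substrate of IMF1.  During seizures the band is recentered by
  `seizure_hum_ratio` (0.64) and amplified by `seizure_amp_gain` (6).
* Seizures: rhythmic sharp spikes (5/s, waning 1.5 s before offset, as
  electrographic seizures do) over the recentered, amplified hum; every
  seizure is followed by a lull (10 s at 0.15× amplitude).
* IIS: classic spike-and-wave morphology — a sharp biexponential transient
  (30–80 ms, 1 mV) followed by a 100 ms after-wave at 80% amplitude.  The
  after-wave and partial-overlap windows populate the lower part of the
  difference histogram's right mode, which is what lets the
  `mean2 + sd2` rule clear them while catching every spike peak.
* Optional pHFO ripples (Gaussian-windowed sinusoid, 350–450 Hz, 40% of
  spike amplitude) on ictal and inter-ictal spikes.
* The whole signal passes a zero-phase 4th-order Butterworth low-pass at
  600 Hz, mimicking the recording chain; zero phase keeps ground-truth
  timing exact.

What the generator does *not* emulate: biophysical network dynamics,
behavioral-state cycles of 12 h recordings, electrode drift and movement
artifacts, multi-channel structure, or the across-animal variability of
real seizures.  Passing tests therefore demonstrate that the pipeline
recovers the structure it assumes, at realistic amplitudes and rates — not
that it would perform identically on any particular animal's data.

# Problem sizes used in validation

The test suite and the acceptance script run the pipeline end to end on:
100 random signals (256–1024 samples) for the reconstruction identity;
twelve ~5 min records with one seizure each (10–60 s) plus one hour-long
seizure-free record for detection; ten ~2 min records with 15 s seizures
for the frequency-ratio recovery (plus three event-free nulls); three
200 s IIS-rich records; 1000 and 2000 replicates for regression
unbiasedness and test calibration.  These sizes give stable estimates while
keeping a full run in the minutes range on a single core.

# Known limitations

* The detectors assume a stationary background within a record; slow state
  changes (sleep/wake) would widen the background mode and, if strongly
  bimodal themselves, could defeat the seizure threshold's D > 2 gate.
* IIS detection requires a genuinely bimodal difference histogram; on
  records with very few IIS and no other amplitude transients the detector
  (correctly) refuses to threshold rather than guessing.
* EMD mode mixing is inherited from the plain algorithm; IMF identity
  across epochs is positional, so occasional mode swaps blur per-IMF
  averages.
* The equivalent-rectangle center frequency is a robust summary of a
  broad, possibly multimodal spectrum, but for strongly bimodal IMF
  spectra (mixing) it can sit between the modes.
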