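Package: lfpemd
Title: Empirical Mode Decomposition Analysis of Epileptic Local Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the analysis of chronic single-channel local field
    potential (LFP) recordings from epileptic tissue: objective detection of
    electrographic seizures, post-ictal lulls and inter-ictal spikes using
    bimodal-histogram thresholds (Ashman's D); empirical mode decomposition
    (EMD) with the S-number sifting criterion; per-IMF spectral
    characterization by the equivalent-rectangle and centroid methods;
    quintile-normalized pre-ictal/ictal/post-ictal frequency and power
    profiles; farthest-point clustering, regression through the origin and
    paired rank statistics; and Z-scored Morlet wavelet time-frequency maps
    for high-frequency oscillations.  Includes a seeded synthetic LFP
    generator with ground-truth event logs for validation, and readers and
    writers for CSV and EDF recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
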