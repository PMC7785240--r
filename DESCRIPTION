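Package: gastrosync
Title: Phase-Locking Analysis of Gastric Rhythms and Brain Resting-State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying phase synchronization between the gastric
    basal electrical rhythm, recorded with cutaneous electrogastrography (EGG),
    and brain resting-state network (RSN) time courses from concurrent
    resting-state fMRI. Implements the EGG preprocessing chain (anti-alias
    low-pass and downsampling, Welch spectral peak detection in the
    normogastric band, narrow zero-phase FIR bandpass, resampling to the BOLD
    rate), Hilbert instantaneous phases and the phase-locking value (PLV), a
    mismatched-run surrogate null with rank-sum inference and
    Benjamini-Hochberg correction, gastric-rhythm stability analysis, and a
    phase-adjusted variance-explained measure based on a von Mises model of
    the phase difference. A synthetic-data generator produces multi-session
    EGG + RSN studies with known coupling structure for validation and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
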