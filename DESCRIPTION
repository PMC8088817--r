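Package: hfomi
Title: Interictal High-Frequency Oscillation and Phase-Amplitude Coupling
    Biomarkers for Epilepsy Surgery Outcome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interictal high-frequency oscillations (HFOs) in
    intracranial EEG with four automated detectors (short-time energy,
    short line length, Hilbert envelope, and the Montreal percentile
    method), verifies detected events on Morlet time-frequency maps to
    separate genuine oscillations from high-pass filtering artefacts of
    sharp transients, and quantifies slow-wave (3-4 Hz) phase to HFO
    amplitude coupling with a mean-vector-length modulation index.
    Channel-level biomarkers can be z-normalized against a normative
    atlas built from the k closest non-epileptic electrode sites, and
    summarized per patient as a subtraction statistic (resected minus
    preserved mean) that quantifies completeness of resection of
    interictally abnormal cortex.  Logistic outcome models with ROC/AUC,
    leave-one-out cross-validation, calibration and rank diagnostics
    relate the biomarkers to post-operative seizure outcome.  A
    synthetic-cohort simulator with planted ground truth supports
    end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    withr,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
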