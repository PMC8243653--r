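Package: pacdetect
Title: Delineation-Free Detection of Premature Atrial and Ventricular
    Beats in Ambulatory ECG
Version: 0.2.0
Authors@R:
    person("pacdetect", "developers", email = "pacdetect@example.org",
           role = c("aut", "cre"))
Description: Detects premature atrial complexes (PACs) and ventricular
    beats in long-term two-lead ECG recordings without any ECG
    delineation. Beats annotated at the R peak are described by
    heart-rate-variability features computed over four time windows and
    by template cross-correlation morphology features extracted from
    fixed windows around the R peak, on both the band-limited ECG and
    the fourth scale of an undecimated quadratic-spline wavelet
    transform. A random forest classifies beats as normal (N),
    supraventricular ectopic (S) or ventricular (V) under a patient-wise
    cross-validation protocol with class-balanced folds and per-class
    training caps. Includes WFDB and plain-text readers, a configurable
    preprocessing chain (resampling, cascaded median-filter baseline
    removal, 35 Hz linear-phase low-pass), and an annotated synthetic
    ECG generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
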