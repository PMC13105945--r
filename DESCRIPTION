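Package: acfc
Title: Amplitude-Amplitude Cross-Frequency Coupling for Physiological Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts simultaneous electromyographic (EMG), electrocardiographic
    (EKG) and respiratory recordings into inter-muscular, cardio-muscular and
    respiratory-muscular coupling matrices, multiplex network maps, coupling
    time series and variability statistics. Implements windowed spectral
    band-power extraction, equal-time Pearson coupling at configurable lag,
    Pan-Tompkins R-peak detection with instantaneous heart-rate series,
    time-frequency breathing-rate extraction, detrended fluctuation analysis,
    magnitude-sign decomposition, Fourier phase-randomization surrogate
    significance testing, and a seeded synthetic-cohort generator with known
    ground-truth coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
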