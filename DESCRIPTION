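Package: facevitals
Title: Contactless Heart Rate and Eye-Blink Rate from Facial Video Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of heart rate from remote photoplethysmography
    (cheek region-of-interest colour traces) and eye-blink rate from
    facial-landmark eyelid distances, together with the laboratory
    reference pipelines (single-lead ECG R-peak detection, vertical EOG
    blink detection) and the device-agreement statistics used to validate
    them (repeated-measures correlation, normality-gated paired tests,
    percentage differences). Includes deterministic synthetic-signal
    generators with ground truth for every input the pipelines consume,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
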