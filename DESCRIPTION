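Package: igradient
Title: Count-Adapted Intensity Gradient for Accelerometer Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the intensity gradient (the log-log slope of time
    accumulated at each physical-activity intensity versus bin intensity)
    from accelerometer data, in three variants: ENMO-based (25 mg bins),
    fine count-based (25 counts per bin) and bin-adjusted count-based
    (100 counts per bin). Includes the supporting processing chain for
    hip-worn ActiGraph-style devices: epoch-level count and ENMO
    summarisation, wear-log masking, Evenson cutpoint classification,
    inter-device lag detection and correction, repeated-measures
    Bland-Altman agreement, intraclass correlation and repeated-measures
    correlation, and a synthetic paired-device data generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
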