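Package: actibed
Title: Annotation and Agreement Analysis of In-Bed Periods from Dual-Site Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolchain for the manual annotation of in-bed periods in raw
    hip- and thigh-worn accelerometer recordings. Derives seven visual signal
    features (posture, activity class, time of day, movement intensity and
    inclination per site) at one-second resolution, exports them as a
    multi-channel IEEE-float WAV for inspection and labelling in Audacity,
    converts Audacity label tracks to and from absolute in-bed events, derives
    reference in-bed events from 30-second EEG sleep-stage epoch records and
    sleep diaries, and quantifies agreement between event sources with
    two-way random-effects intraclass correlation coefficients and
    Bland-Altman limits of agreement, each with 95 percent confidence
    intervals. A seeded simulator generates multi-day two-site recordings with
    known in-bed intervals, rater annotations, diaries and epoch files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
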