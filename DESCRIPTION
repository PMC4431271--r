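Package: adlsim
Title: Synthetic Sensor Datasets for Activities of Daily Living
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic simulator of human activities of daily living in a
    dense-sensing smart environment. Activity and behaviour models for one
    resident are described in a plain-text ADL script (sensor-activation
    patterns with occurrence probabilities and Gaussian time lapses, day-level
    behaviour models built from time-slotted sequences and probabilistic
    alterations, and per-hour positive sensor noise); the environment (objects,
    attached sensors, per-sensor-type missing-noise probabilities) is described
    in a JSON context-knowledge file. The simulator emits labelled, timestamped
    sensor-activation datasets in CSV, with noise events carrying the
    distinguished label None and activity boundaries marked. A companion
    evaluation procedure scores the similarity of two event datasets by binning
    per-sensor occurrence counts into fixed intervals, testing each sensor's
    2xK contingency table with Fisher's exact test (exact enumeration with a
    seeded Monte-Carlo fallback) and averaging the per-sensor p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
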