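Package: paqc
Title: Quality Assurance for Duplicate-Channel Optical Particle Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating low-cost optical particle monitors that
    carry two independent Plantower-style sensing channels, such as the
    PurpleAir PA-II. Converts cumulative size-bin particle counts to PM1 and
    PM2.5 mass concentration with the open ALT-CF3 algorithm (spherical
    volume times density times a calibration factor), quantifies duplicate
    channel precision |a-b|/(a+b) and the data loss caused by the vendor
    practice of reporting zero below a threshold, estimates limits of
    detection for continuous paired sensors from the mu/sigma > 3 criterion,
    fits precision-drift regressions, summarises log-normal concentration
    structure on normal-probability axes, and compares sensor output to
    co-located reference monitors as ratios with propagated standard errors.
    A seeded synthetic-data generator produces realistic dual-channel indoor
    and outdoor monitor streams with known ground truth so that every stage
    of the pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
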