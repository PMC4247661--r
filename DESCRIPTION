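Package: actiwear
Title: Accelerometer Wear-Time Algorithms, Cut-Point Summaries and
    Method Agreement for Mail-Based Cohort Protocols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Processes minute-epoch triaxial accelerometer count data
    (ActiGraph-style) for physical-activity epidemiology. Implements the
    Troiano and Choi non-wear detection algorithms on vertical-axis and
    vector-magnitude counts, participant monitor-log parsing with AM/PM
    imputation, detailed-log and limited-log (dates-only) wear masks,
    sedentary/light/MVPA cut-point classification, valid-day and cohort
    summaries, and method-agreement statistics (exact Wilcoxon signed-rank,
    Bland-Altman limits of agreement). Includes a synthetic-cohort
    generator with ground truth that emulates mail-based protocols,
    including in-transit "mail noise" that zero-run algorithms misread
    as wear.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
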