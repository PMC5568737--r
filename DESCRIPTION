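Package: phenothermal
Title: Thermal-Time Models of Phenophase Onset from Status-Format Phenology Observations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates universal accumulated growing degree day (AGDD) onset
    thresholds for species-by-phenophase combinations from status-format
    ("yes"/"no") phenology observations and daily temperature series, in the
    style of the USA National Phenology Network's thermal-time analyses.
    Provides status-record filtering (prior-"no" window, day-of-year cutoffs,
    region exclusion), calibration/validation splitting, null models and
    Nash-Sutcliffe model efficiency, a spring-temperature climate envelope for
    assessing geographic extensibility, threshold-crossing day-of-year maps on
    gridded temperature stacks, and a synthetic-data generator with known
    ground truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
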