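Package: chronospd
Title: Summed Probability Distributions from Radiocarbon and Tree-Ring Dates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building annual-resolution summed probability
    distributions (SPDs) from archaeological radiocarbon and
    dendrochronological date collections and comparing them against
    independent population reconstructions. Includes IntCal-style
    calibration-curve parsing, probabilistic radiocarbon calibration with
    highest-density regions, rule-based cleaning of date tables with audit
    trails, single-linkage site-phase binning, degenerate (single-year)
    densities for tree-ring cutting dates, Gaussian smoothing,
    area-equalized scaling against period-resolved population series, and a
    synthetic-data generator with known demographic truth for end-to-end
    validation.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
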