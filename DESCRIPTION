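Package: localuse
Title: Decay-Weighted Local Pesticide Use, Spatial Durbin Models, and
    Measurement-Error Bootstrap for Distributional Exposure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distributional environmental-justice analysis of
    point-source pesticide use. Aggregates geocoded use records to section
    centroids, links them to census geographies through an exponential
    characteristic-travel-distance (CTD) decay model, fits spatial Durbin
    regressions of log local use on demographic covariates by maximum
    likelihood with k-nearest-neighbor spatial weights, summarises effects as
    LeSage-Pace direct/indirect/total impacts, and propagates survey margins
    of error through a parametric measurement-error bootstrap. Includes a
    synthetic-data generator with a known spatial Durbin data-generating
    process so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
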