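Package: warewind
Title: Wind-Rotated Satellite NO2 Composites, Truck Traffic, and Exposure
    Disparities Near Point Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify local nitrogen dioxide (NO2) enhancements
    around point facilities such as warehouses from daily gridded satellite
    retrievals.  Daily near-facility windows are rotated into a common
    wind-aligned frame using vector-mean overpass winds, composited across
    days and facilities, and summarised by an upwind-edge enhancement
    statistic with downwind peak displacement.  Road-segment traffic counts
    are converted to gridded vehicle kilometres travelled and related to
    facility characteristics by decile-binned regressions; census-tract
    demographics support population-weighted exposure and siting-disparity
    analyses.  A seeded synthetic-scenario generator with recorded ground
    truth makes every stage verifiable by parameter recovery without any
    proprietary inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
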