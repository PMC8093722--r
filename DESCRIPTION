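Package: freeroam
Title: Spatial Ecology of Free-Roaming Dogs from GPS Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for motion-triggered GPS collar data from
    free-roaming domestic dogs. Reads per-dog logger exports, projects
    coordinates to UTM, removes fixes implying implausible travel speeds,
    computes daily distance travelled and time spent within the household
    compound, estimates utilization distributions with a movement-based
    (biased random bridge) kernel to obtain core and extended home-range
    isopleths and their centroids, and fits random-intercept mixed models
    for risk-factor analysis with intracluster correlation. Includes a
    two-state Ornstein-Uhlenbeck trajectory simulator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
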