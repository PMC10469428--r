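Package: movestates
Title: Behavioural-State Decoding and Foraging Linkage for Marine Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline from raw satellite-telemetry locations and
    dive records to behavioural inference about long-distance movements.
    Implements quality-control filtering of mixed Fastloc-GPS/Argos tracks,
    continuous-time correlated random walk state-space interpolation to hourly
    positions, a two-state (area-restricted search vs. Transit) hidden Markov
    model on step lengths and turning angles with multi-start fitting and
    degenerate-fit screening, seasonal 50% kernel utilization distributions for
    separating residency from long-distance movement phases, and hourly
    foraging-dive summaries by state and season. Includes a seeded synthetic
    track-and-dive generator with the statistical structure the pipeline
    assumes, so every stage is testable without proprietary tag data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    geosphere,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
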