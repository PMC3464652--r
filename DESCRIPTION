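Package: gastroMap
Title: Mapping and Analysis of Multi-Electrode Gastrointestinal Slow-Wave Recordings
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for taking multi-electrode serosal gastrointestinal
    recordings from raw extracellular signals to activation-time marks,
    clustered wavefront cycles, interpolated isochronal activation maps,
    conduction-velocity fields, amplitude maps and time-interval (frequency)
    maps, plus propagation animations. Includes a falling-edge
    variable-threshold (FEVT) event detector, region-growing cycle clustering
    stabilised by a continuously refit second-order activation-time surface
    (REGROUPS), a two-stage spatial interpolation scheme (SIV), readers and
    writers for BioSemi BDF and delimited-text signals, and a synthetic
    slow-wave generator with exact ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
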