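Package: dropsfx
Title: Analysis Pipeline for Drop-on-Demand Serial Femtosecond Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing drop-on-demand serial femtosecond
    crystallography (SFX) data streams: flat-detector geometry and
    resolution conversions, a synthetic diffraction-frame simulator with
    Poisson crystal occupancy and ground-truth event tables, Bragg peak
    finding and hit classification on masked detector frames, spot
    prediction matching and misindexing (cross-contamination) audits,
    run-level and time-binned hit and indexing-rate statistics, radially
    averaged Bragg-intensity quality profiles, and droplet sample
    consumption and concentration modelling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    graphics
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
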