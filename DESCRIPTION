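Package: rhizO2
Title: Ratiometric Planar-Optode Oxygen Mapping and Rhizosphere Anoxic
    Microsite Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts dual-channel (sensor/reference) luminescence optode
    images into calibrated dissolved-oxygen maps via a two-point exponential
    calibration, extracts oxygen profiles along user-defined polylines around
    growing root tips, and quantifies anoxic microsites: hypoxic and suboxic
    region lengths, normalized longitudinal profiles, transverse decreases,
    timelapse root growth rates versus oxygen minima, suboxic microsite
    volume and microbial exposure time, and linear mixed-effects variance
    partitioning across treatments. Includes a seeded synthetic-scene
    generator (Gaussian depletion plume with analytic threshold crossings)
    so every stage is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
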