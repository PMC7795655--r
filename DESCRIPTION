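Package: paflux
Title: Fluence-Compensated Photoacoustic Oxygen Saturation Imaging for LED-Array Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative oxygen-saturation (sO2) imaging for dual-wavelength
    LED-based photoacoustic (PA) systems. Builds the inclined LED-array source
    geometry of an AcousticX-style probe, runs a voxel Monte-Carlo photon
    transport simulation to estimate wavelength-dependent light fluence inside
    tissue, segments co-registered B-mode ultrasound images into tissue masks
    that define the simulation medium, normalizes dual-wavelength PA images by
    the simulated fluence, and unmixes the compensated images into
    deoxy-/oxy-hemoglobin concentrations and per-pixel sO2 maps. Includes a
    synthetic phantom generator (blood-filled tubes at depth, two-slab media,
    speckled ultrasound) so the full pipeline can be exercised and validated
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
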