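Package: holopm
Title: Lensfree Holographic Sensing of Particulate Matter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of lensfree in-line holograms for
    portable air-quality monitoring. Renders synthetic holograms of
    nanolens-enhanced aerosol particles (100 nm to 1 um) deposited on a
    vapor-condensed film over a monochrome sensor, reconstructs them by
    angular-spectrum back-propagation with autofocus, detects and sizes
    particles through an iterative multi-threshold phase procedure with
    twin-image removal and a fitted phase-to-diameter calibration, and
    converts time-resolved particle counts into size-resolved PM mass
    concentrations with collection-efficiency estimation and EPA-style
    performance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
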