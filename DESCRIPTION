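Package: phasemorph
Title: Label-Free Cell Morphometry from Quantitative Phase Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid, label-free measurement of cell and nucleus sizes from
    quantitative phase microscopy images. Simulates phase maps of nucleated
    cell phantoms (nested-sphere refractive-index models), computes lateral
    forward-difference phase gradients and modulus-squared edge maps, detects
    paired jump points along one-dimensional gradient profiles, and converts
    jump-pair pixel separations into physical distances with error statistics
    against known ground truth. Includes SNR-controlled Gaussian noise
    injection for robustness studies, 32-bit float TIFF and CSV phase-map
    input/output with pixel calibration, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
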