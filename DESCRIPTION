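Package: holorec
Title: Lens-Free In-Line Holography Simulation and Twin-Image-Free Phase Recovery
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for digital in-line holographic microscopy of dense,
    strongly scattering transmissive specimens. Simulates hologram formation
    with an angular-spectrum scalar diffraction engine, generates seeded
    synthetic specimen phantoms and multi-height hologram stacks, reconstructs
    complex object fields with the classical transport-of-intensity
    initialised multi-height iterative phase-retrieval algorithm, and trains a
    compact multi-scale residual convolutional network that recovers
    twin-image-free phase and amplitude from a single back-propagated
    hologram. Includes structural-similarity and per-cell phase-integral
    evaluation, a defocus-tolerance sweep, plain TIFF/PNG intensity image I/O,
    and a scriptable pipeline front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
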