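Package: difftomo
Title: Full-View Optical Diffraction Tomography by Backpropagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs two- and three-dimensional refractive-index maps of
    cell-like phantoms from full-view complex-field sinograms. Implements the
    backpropagation algorithm for optical diffraction tomography under the
    Born and Rytov approximations, with filtered backprojection (inverse Radon
    transform) as the straight-ray baseline. Includes generators for
    three-compartment cell phantoms, scalar forward models (ray-integral,
    Fourier-diffraction Born, Rytov) with a brute-force Green's-function
    oracle, angular-spectrum refocusing with gradient-metric autofocus,
    quality-guided 2D phase unwrapping, normalized RMS and total-variation
    reconstruction-error metrics, and deterministic parameter-sweep drivers
    for projection count, refractive-index contrast and object size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
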