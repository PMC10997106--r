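Package: emccdpia
Title: Photophysical Image Analysis for EMCCD Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic analysis of images recorded with electron-multiplying
    charge-coupled device (EMCCD) cameras. Models the full camera noise chain
    (Poisson photon arrivals, Gamma-distributed electron multiplication,
    Gaussian readout noise and integer rounding) through its closed-form
    characteristic function, inverts it numerically to obtain exact count
    distributions, estimates camera chip parameters from mean-variance
    calibration stacks, fits the background illumination strength by truncated
    maximum likelihood with chi-square goodness-of-fit model selection, and
    performs unsupervised image thresholding with a priori misclassification
    rates. Includes a gap-rule segmentation post-processor with per-region
    background p-values, a forward simulator for synthetic scenes and
    calibration data, and a tiled whole-image pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    igraph,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
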