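Package: phantomspread
Title: Telegraph-Equation Modelling of Marker Spread in Hydrogel Brain Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and quantifies the passive spread of an opaque marker
    from a microvessel-mimicking channel into a collagen hydrogel phantom of
    brain parenchyma. Implements a modified Cattaneo (telegraph) transport
    model with a first-order sink term, explicit finite-difference solvers on
    2D Cartesian and axisymmetric radial grids, the rescaled-relaxation
    diagnostic that linearises normal 2D disk diffusion, estimation of the
    ballistic-to-diffusive crossover time, least-absolute-deviation fitting of
    the transport parameters to central-concentration traces, and the full
    image-quantification chain from 8-bit grayscale time-lapse stacks to
    normalized radial profiles and center traces. A synthetic-data generator
    emulates the experimental recordings so that every pipeline stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
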