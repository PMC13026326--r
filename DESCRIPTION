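Package: ncopyr
Title: Limiting-Component Quantification of qPCR Amplification Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of raw (non baseline-corrected) qPCR amplification
    curves with the limiting-component quantification method. Calls the
    third-derivative-zero quantification cycle (TD0) without a fluorescence
    threshold, estimates per-reaction baseline and PCR efficiency by
    iterative baseline bisection over the exponential phase, and converts
    TD0 plus the per-target mean efficiency into absolute starting copy
    numbers (Ncopy) under primer-limited or dye-limited regimes. Includes
    the full experiment pipeline (technical-replicate quality control,
    dilution-series efficiency, single-standard calibration, inter-run
    correction, geNorm reference-gene validation, reference normalization
    and group statistics), a mechanistic amplification-curve simulator with
    ground truth for validation, RDES-style delimited table import/export
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    splines,
    deSolve,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
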