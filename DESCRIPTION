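Package: platekit
Title: Analysis of Microbial Growth and Fluorescence from Plate-Reader Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing 96-well plate-reader time courses of optical
    density (OD) and fluorescence. Corrects OD for the non-linear instrument
    response at high cell density using a dilution-series calibration curve,
    subtracts media blanks, and removes cellular autofluorescence either by
    two-channel linear spectral unmixing (for GFP) or by matching the
    fluorescence of an untagged strain at the same OD. Specific growth rates
    and their time derivatives are inferred non-parametrically with Gaussian
    process regression (Matern 5/2 by default) with analytic derivative
    posteriors, yielding summary statistics (maximal and local maximal growth
    rate, lag time, maximal OD) with bootstrapped errors. Includes multi-plate
    meta-analysis on a common time grid, Monod curve fitting for
    nutrient-limited growth, an OD-based proxy for residual glucose, a
    synthetic-plate generator with known ground truth, and a reproducible
    pipeline runner with a plain-text run log.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
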