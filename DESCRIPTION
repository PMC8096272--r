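Package: g4twist
Title: Fluctuation Fingerprints of G-Quadruplex Folding in Supercoiled DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of magnetic-tweezers force-extension experiments on
    negatively supercoiled DNA tethers carrying G-quadruplex (G4) forming
    promoter sequences. Provides a calibrated synthetic trace generator
    (three-state plectoneme / G4-intermediate / denaturation-bubble occupancy
    model with telegraph hopping and bead noise), worm-like-chain fitting of
    untwisted force-extension curves, extension-variance profiling with
    single/double peak classification and characteristic-force extraction,
    logistic steepness statistics with Gaussian-mixture analysis, and an
    energy ledger quantifying the free-energy gain that G4 folding confers on
    torsional duplex opening.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    mclust,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllClasses.R'
    'AllGenerics.R'
    'energetics.R'
    'wlc.R'
    'synthetic.R'
    'fluctuation.R'
    'g4twist-package.R'
    'io.R'
    'steepness.R'
    'pipeline.R'
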