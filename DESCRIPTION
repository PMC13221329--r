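Package: irscreen
Title: Gaussian Deconvolution and Polymer Band Screening for ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory screening of polymer-compatible spectral features in
    attenuated total reflection Fourier-transform infrared (ATR-FTIR) spectra
    of environmental samples. Provides asymmetric-least-squares baseline
    correction, min-max normalization and region segmentation; multi-Gaussian
    deconvolution of overlapping spectral regions with automatic component-count
    selection under an adjusted R-squared criterion; matching of fitted band
    centers against a configurable polymer reference-band library with a fixed
    wavenumber tolerance; conjunctive polymer-compatibility rules producing a
    site-by-polymer occurrence matrix; and a synthetic spectrum generator with
    known ground truth for validation. Reads and writes delimited and simple
    JCAMP-DX spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    signal,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'bands.R'
    'deconvolve.R'
    'irscreen-package.R'
    'jcamp.R'
    'preprocess.R'
    'screen.R'
    'spectra-io.R'
    'synthetic.R'
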