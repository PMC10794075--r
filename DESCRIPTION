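Package: ftirsugars
Title: Sugar and Fructo-Oligosaccharide Quantification from ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric quantification of glucose, fructose, sucrose and the
    fructo-oligosaccharides 1-kestose (GF2), nystose (GF3) and
    fructofuranosyl nystose (GF4) in citrus juices from mid-infrared
    (ATR-FTIR) absorbance spectra. Implements the Beer-Lambert
    simultaneous-equation method with fixed pure-water intercepts and
    exhaustive wavenumber-subset search, Savitzky-Golay second-derivative
    preprocessing, band-assignment driven wavenumber selection (full-region,
    own-component and multi-component models), and PLS-1 (NIPALS) regression
    with grouped cross-validation. A synthetic ATR-FTIR fixture generator
    (Gaussian band libraries over a water background, enzymatic
    transfructosylation time-courses, fructo-oligosaccharide addition
    designs) provides ground-truth data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
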