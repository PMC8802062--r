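Package: pecancolor
Title: Kinetics of Pecan Nutmeat Color Degradation During Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling postharvest color change of pecan nutmeats
    stored under controlled temperature and relative humidity. Fits zero-order
    (linear) decay of hue and first-order (exponential) decay of lightness and
    chroma against storage time, estimates Arrhenius activation energies and
    Q10 temperature coefficients from the fitted rate constants, and predicts
    the number of storage days required to reach a target USDA color grade.
    Ships a digitized six-grade USDA pecan color scale with sRGB, CIELAB and
    LCh coordinates plus the conversions among those spaces, published
    reference rate tables for three cultivars across a 3 temperature by 4
    relative-humidity storage matrix, and a synthetic storage-experiment
    generator with a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
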