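Package: fracAD
Title: Fractal-Fractional Dynamics of Alzheimer's Disease Cell Populations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Forward simulation of a seven-population compartmental model of
    Alzheimer's disease (reactive and quiescent astrocytes, amyloid-beta
    fibrils, pro- and anti-inflammatory microglia, surviving and dead
    neurons) under a fractal-fractional Caputo derivative. Implements the
    explicit two-step-Lagrange fractional Adams-Bashforth product-integration
    scheme with closed-form weights, closed-form and matrix-exponential
    oracles (Mittag-Leffler function, Beta-integral solutions for power-law
    forcing), Ulam-Hyers stability constants with a uniqueness certificate,
    and a (p,q) order-sweep driver with plain-text trajectory output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
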