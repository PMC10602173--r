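Package: furrowsim
Title: Viscous Force-Balance Modelling of Ventral Furrow Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates apical constriction mechanics during Drosophila ventral
    furrow formation with a quasi-static viscous force-balance model driven by
    spatiotemporal actomyosin tension profiles. Provides a one-dimensional
    contraction-rate solver with closed-form oracles, synthetic myosin profile
    generators (ramping envelopes, Ornstein-Uhlenbeck cell-to-cell fluctuations,
    and pulse trains emulating wild-type, C-GAP RNAi, Spn27A RNAi and twist RNAi
    conditions), cross-sectional furrow-shape reconstruction with failure
    classification, a two-dimensional Fourier spectral solver, parameter
    inference, ensemble statistics, and power-spectral analysis of pulsatile
    myosin signals.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
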