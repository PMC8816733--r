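Package: cosolvr
Title: Cosolvency Solubility Models and PC-SAFT Solid-Liquid Equilibria
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measurement-to-model workflow for drug solubility in binary
    aqueous-cosolvent mixtures. Implements HPLC calibration and inverse
    prediction, the log-linear (Yalkowsky), Jouyban-Acree (fitted,
    pre-trained and Abraham-descriptor-extended) and modified Wilson
    cosolvency models with a single fitting interface, a PC-SAFT equation
    of state with 2B association (hard-chain, dispersion and association
    Helmholtz contributions, density solving, fugacity and activity
    coefficients), an iterative solid-liquid-equilibrium solubility
    solver, mean-relative-deviation model scoring, diffractogram
    crystallinity indices, and seeded generators for synthetic solubility,
    chromatography and diffraction data. Ships the acetylsalicylic acid in
    ethanol + water reference dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
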