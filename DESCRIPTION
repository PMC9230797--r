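Package: tegopbpk
Title: Coupled PBPK/PD Simulation of Tegoprazan and Its Metabolite M1
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A whole-body physiologically based pharmacokinetic (PBPK) model
    for the potassium-competitive acid blocker tegoprazan coupled to an
    indirect-response pharmacodynamic model of intragastric pH. Includes
    in-vitro parameter derivation (microsomal and recombinant-CYP substrate
    depletion, Caco-2 permeability), a nine-segment gastrointestinal
    absorption-transit model with diffusion-layer dissolution and pH-dependent
    solubility, Rodgers-Rowland tissue partitioning with Kp-scalar
    calibration, a minimal PBPK model with single adjusting compartment for
    the metabolite M1, virtual-population simulation, non-compartmental
    analysis with predicted/observed verification ratios, and synthetic
    observed-data generation for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
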