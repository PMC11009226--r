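Package: chex2dir
Title: Two-State Amide-Water Hydrogen-Bond Exchange from FTIR and 2D IR
    Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the equilibrium and kinetics of exchange between
    strongly and weakly hydrogen-bonded states of a peptide amide carbonyl
    in water. Provides second-derivative detection and two-component Voigt
    decomposition of the amide-I infrared band, transition-dipole-corrected
    van't Hoff thermodynamics, the chemical-exchange two-dimensional infrared
    (2D IR) cross-peak protocol (window normalization, reference subtraction,
    exponential kinetics, Arrhenius and detailed-balance analysis), radial
    distribution functions and geometric hydrogen-bond statistics for
    molecular trajectories, and a synthetic-data generator that emulates the
    instrument and a toy hydration trajectory so that every analysis stage is
    testable end to end without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
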