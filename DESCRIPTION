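Package: lipidcycles
Title: Thermodynamics of Protein-Lipid Binding from Native Mass Spectrometry
    Titrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of variable-temperature native mass spectrometry
    lipid-titration data for membrane proteins. Fits sequential
    ligand-binding models to deconvoluted mole-fraction titrations with an
    exact free-ligand mass balance, extracts thermodynamic signatures
    (free energy, enthalpy, entropy and heat capacity of binding) by linear
    and nonlinear van't Hoff analysis, and performs double and triple
    thermodynamic mutant-cycle coupling analysis with quadrature error
    propagation. Includes a synthetic-data generator that emulates the
    replicate structure and noise of deconvoluted native MS titrations, and
    the published equilibrium-constant and coupling tables for the ABC
    transporter MsbA binding the lipopolysaccharide precursor KDL as
    reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
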