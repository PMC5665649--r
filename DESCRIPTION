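Package: sedimer
Title: Sedimentation-Velocity Analysis of Competitive Homo- and Hetero-Dimerization
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fluorescence-detected sedimentation velocity (FDS-SV)
    analytical ultracentrifugation studies of reversible protein dimerization.
    Provides a finite-volume Lamm equation solver for sector-shaped cells,
    forward simulation of sedimentation boundaries for reversibly reacting
    monomer-dimer and competitive homo/hetero-dimer systems (finite-rate and
    instantaneous-equilibrium kinetics), diffusion-deconvoluted c(s)
    sedimentation coefficient distributions by regularized non-negative
    inversion, transport-method signal-weighted average sedimentation
    coefficients (sw), mass-action isotherm models with dimerization-incompetent
    fractions, nonlinear isotherm fitting with error-projection (profile
    chi-square, F-statistic) confidence intervals, direct boundary fitting for
    dissociation rate constants, free-energy maps, and a synthetic-data
    generator emulating tracer-titration and dilution designs for ionotropic
    glutamate receptor amino-terminal domains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, pracma, quadprog, jsonlite
Suggests: testthat (>= 3.0.0), optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
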