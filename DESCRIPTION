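Package: bilayerlab
Title: Analysis of Drug Effects on Model Lipid Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying small-molecule interactions with model
    lipid membranes from planar-bilayer electrophysiology, ratiometric
    fluorimetry and differential scanning calorimetry. Converts
    carrier-mediated membrane conductance ratios to boundary-potential
    changes via the Boltzmann relation, fits concentration dependences
    with the Langmuir adsorption isotherm (linearized and nonlinear),
    estimates dipole-potential changes from di-8-ANEPPS dual-excitation
    ratios, idealizes gramicidin A single-channel records and fits
    conductance histograms with normal mixtures under a chi-square
    goodness-of-fit criterion, measures steady-state macroscopic
    (nystatin) current ratios, and extracts lipid melting features
    (pretransition, main transition temperature, half-width) from
    thermograms. Seeded synthetic-data generators with known ground
    truth make every stage testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    signal,
    zoo,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
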