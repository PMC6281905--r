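Package: esterkin
Title: Kinetic Stability Analysis of Arsenate and Phosphate Esters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing toolkit for comparative hydrolysis kinetics of
    arsenate and phosphate esters. Reads XYZ and PDB structures, perceives
    bonds from covalent radii, measures internal coordinates and builds
    reactant-versus-transition-state parameter tables, performs Kabsch
    superposition, converts harmonic frequencies to rigid-rotor
    harmonic-oscillator thermal corrections and activation free energies,
    evaluates Eyring transition-state-theory rate constants and half-lives,
    decomposes barriers with the activation strain (distortion/interaction)
    model, classifies biological esters, substitutes arsenic for backbone
    phosphorus, partitions structures into two-layer QM/MM regions, and
    assembles comparative stability reports. Seeded synthetic-data
    generators provide geometry, frequency and energy fixtures with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
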