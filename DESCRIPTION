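Package: ddgbind
Title: Structure-Based Prediction of Binding Free Energy Changes upon Point Mutation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts the change in protein-protein binding free energy caused by a
    single amino-acid substitution using an MM/PBSA-style energy decomposition
    (molecular-mechanics Lennard-Jones and Coulomb terms, Generalized-Born polar
    solvation and surface-area nonpolar solvation) evaluated on energy-minimized
    wild-type and mutant complexes. Classifies mutation sites by interface location
    (core, support, rim, interior, surface) from relative solvent accessibility in
    the monomer and the complex, provides in-silico side-chain replacement with a
    discrete rotamer search, confusion-matrix benchmarking of predicted against
    experimental energy changes under five threshold scenarios, and case-study
    protocols for discriminating disease-associated from benign variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
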