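Package: peptidimer
Title: Thermodynamics of beta-Hairpin Peptide Dimerization in Detergent Micelles
Version: 0.1.0
Authors@R: person("peptidimer", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for NMR-monitored dimerization of beta-hairpin
    antimicrobial peptides in detergent micelles: Lorentzian decomposition of a
    reporter resonance into monomer and dimer components, transverse-relaxation
    correction of signal integrals, a micellar-solvent equilibrium model linking
    dimer populations to detergent concentration, van't Hoff decomposition of the
    dimerization free energy, and sequence-level physicochemical descriptors with
    composite descriptor-activity correlation. A seeded synthetic-data module
    generates ground-truthed titration and temperature series so that every stage
    of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    rlang,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
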