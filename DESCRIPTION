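Package: mcboolnet
Title: Multi-Cellular Boolean Network Modelling, Calibration and In Silico
    Knockout Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating multi-cellular Boolean
    models of diseased tissues such as the rheumatoid-arthritis synovium.
    Reads and writes logical models in SBML-qual, extracts
    phenotype-upstream submodels, fuses cell-specific models through
    evidence-filtered ligand-receptor interactions, enumerates all steady
    states over free-input combinations with a constraint-propagation
    fixpoint solver, calibrates models against discretized differential
    expression profiles, and screens single and double in silico knockouts
    for phenotype reversal and synergy. Includes a seeded synthetic-data
    generator (random Boolean models with planted steady states, noisy
    observed profiles, intercellular interaction tables and therapeutic
    target tables) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
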