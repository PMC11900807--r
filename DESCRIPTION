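Package: orscreen
Title: Structure-Based Virtual Screening Toolkit for Insect Odorant Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for structure-based virtual screening of odorant
    receptor ligands from docking-score tables: odorant-likeness
    physicochemical filtering of molecule libraries, ligand-efficiency
    rescoring of docking scores (LE, LEln, LESA), ROC/enrichment-factor
    calibration of scoring functions against receptor-activity panels,
    promiscuity-based decoy triage of screened libraries, chemical-space
    clustering of candidates with circular fingerprints, selection of
    purchasable cluster representatives, and a binding-pocket descriptor
    regression of receptor tuning breadth. Includes seeded synthetic-data
    generators emulating every input so the full workflow is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
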