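Package: digestate
Title: Mass Balances, Methane Potentials and Survey Statistics for
    Full-Scale Anaerobic Digestion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes digestate from full-scale biogas plants.
    Computes gas-volume-corrected mass balances across digesters and
    post-digesters (volatile-solids reduction, per-macromolecule
    degradation efficiencies, microbial-biomass protein correction,
    nitrogen mineralization), theoretical methane potentials from
    macromolecule and volatile-fatty-acid contents via Buswell
    stoichiometry, free-ammonia speciation from ammonium, pH and
    temperature, and the survey statistics layer (scaling, Ward
    clustering, principal components, pairwise Pearson scans).  A
    seeded synthetic-plant generator forward-simulates multi-stage
    plants with known ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
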