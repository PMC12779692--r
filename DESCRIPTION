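Package: silicotox
Title: In Silico Toxicological Assessment Chain for Cholinesterase-Targeting Insecticide Candidates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a ligand- and structure-based computational
    toxicology chain for small-molecule insecticide candidates such as
    (thio)semicarbazones: conceptual-DFT global reactivity descriptors from
    frontier orbital energies, condensed Fukui / dual / multiphilic site
    reactivity from three-state atomic charge populations, ECOSAR-style
    aquatic toxicity estimation and classification, Arnot-Gobas
    bioconcentration, CNS multiparameter optimization (MPO) desirability
    scoring, Manhattan conformer similarity, and molecular-dynamics
    post-processing (RMSD, RMSF, hydrogen-bond occupancy, MM/GBSA binding
    energy totals). Quantum-chemistry, docking and MD engines are out of
    scope; a seeded synthetic-data generator emulates their outputs with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
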