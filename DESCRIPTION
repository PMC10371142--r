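Package: oximescreen
Title: In Silico Screening of Phenoxyalkyl Pyridinium Oxime Reactivators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A virtual-screening framework for discovering broad-spectrum
    antidotes to organophosphate (OP) anticholinesterase poisoning within the
    substituted phenoxyalkyl pyridinium oxime (SPPO) chemotype. Decomposes
    tested SPPOs into shared scaffolds and positioned R-groups, enumerates a
    rule-constrained combinatorial virtual library, trains gradient-boosted
    classifiers of acetylcholinesterase reactivation (on paired
    reactivator:challenge descriptors) and of blood-brain-barrier
    permeability (from logBB), and runs a sequential screening funnel ending
    in a pluggable synthesizability filter. Low-level cheminformatics
    (SMILES, descriptors, substructure matching) is delegated to RDKit
    through a batched Python helper; a synthetic-fixture generator emulates
    all external inputs so the pipeline runs and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.8) with RDKit importable by the interpreter
    found via options(oximescreen.python), OXIMESCREEN_PYTHON, or `python` on
    the PATH
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    ChemmineR,
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
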