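Package: molcurate
Title: Standards-Based Curation of Computed Molecular Structure Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating, normalizing and re-packaging legacy
    collections of computed molecular structures. Reads and writes two
    dialects of Chemical Markup Language (CML), reconciles formal-charge
    declarations and derives electron counts and spin multiplicities for
    fully explicit semi-empirical quantum-chemistry input decks, perceives
    atom connectivity from Cartesian coordinates by covalent-radius rules,
    obtains InChI identifiers through the OpenBabel reference binding and
    dissects them into layers, classifies structure-version triplets by
    InChI concordance, and assembles repository-ready deposition bundles
    (METS manifests, OAI-ORE resource maps, SWORD archives) with
    DataCite-crosswalked metadata. A seeded synthetic-corpus generator
    provides ground-truth fixtures for every pipeline stage.
License: MIT
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    digest,
    zip,
    igraph,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
SystemRequirements: OpenBabel (obabel on the PATH) for InChI generation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
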