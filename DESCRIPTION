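Package: precompose
Title: Compile Pre-Composed Phenotype Ontologies from Design Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds fully classified, quality-controlled releases of a
    pre-composed phenotype ontology from an anatomy/quality ontology in OBO
    format, a library of DOSDP-style design patterns in YAML, and TSV
    instantiation tables. Entity terms are selected by relation-restricted
    traversal (is_a and part_of, never develops_from) under configurable
    exclusion lists and applicability filters; stable identifiers are minted
    deterministically; the complete is_a hierarchy is derived purely from
    logical definitions by structural subsumption over an EL-style expression
    fragment; releases are serialized to OBO and graph JSON, checked for
    duplicate labels and duplicate logical definitions, and diffed against
    previous releases so no term ever silently disappears.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
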