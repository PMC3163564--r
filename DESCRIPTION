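Package: lipidclassr
Title: Structure-Based Functional Group Annotation and Ontology
    Classification of Lipids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Annotates SMILES-described small molecules with unique,
    non-overlapping functional-group occurrences detected by SMARTS
    substructure matching, builds a closed-world structural profile, and
    classifies each molecule against formally defined lipid classes
    expressed as intersections of existential and qualified-cardinality
    restrictions on the 'has proper part' relation.  Satisfied classes
    are pruned to the most specific set and mapped to LIPID MAPS class
    identifiers and categories.  Ships an editable SMARTS pattern
    library and an eicosanoid class ontology fixture, Turtle RDF input
    and output in the SIO vocabulary, an exact/partial/mismatch
    evaluation procedure against gold-standard assignments, and a
    deterministic synthetic eicosanoid generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
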