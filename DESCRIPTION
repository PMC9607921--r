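Package: ehr13606
Title: Communicating Patient-App Data as EN/ISO 13606 Extracts to an
    Ontology-Based Clinical Repository
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-model toolkit for turning patient-generated health data
    (side-effect reports and daily activity from a mobile app) into
    EN/ISO 13606 electronic health record extracts. Implements a compact
    subset of the 13606 reference model, machine-checkable entry
    archetypes with a validation engine, SNOMED CT terminology binding
    driven by a JSON mapping config, bit-stable XML serialization with a
    published XSD, an ontology-based clinical repository stand-in
    (Turtle output, idempotent ingestion, record identifiers), and a
    synthetic cohort generator that emulates a 62-patient pilot with
    dropouts, never-users and intermittent reporting so the whole
    pipeline is reproducible without access to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stringi,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
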