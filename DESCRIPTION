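Package: oncodw
Title: Desk-Scale Clinical Data Warehouse for Translational Oncology Research
Version: 0.1.0
Authors@R:
    person("Onco", "Warehouse Contributors", email = "oncodw@example.org",
           role = c("aut", "cre"))
Description: A self-contained, fully testable re-implementation of the core of an
    i2b2-style translational research platform for a breast-cancer cohort:
    rule-based information extraction from semi-structured pathology reports
    (SNOMED morphology codes, TNM stage, grade, hormone receptors, Ki-67,
    HER-2), anonymized biobank synchronization with DataMatrix-style barcode
    payloads and a segregated lookup table, a star-schema observation-fact
    warehouse with hierarchical concept paths, boolean panel patient-set
    queries with ontology expansion, and biobank-info and Kaplan-Meier
    analysis plug-ins.  A seedable synthetic-cohort generator emulates the
    pathology unit, hospital information system and biobank sources with
    ground truth, so every layer is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
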