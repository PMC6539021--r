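Package: iotqa
Title: Quality Assessment and FHIR Interoperability for IoT Medical Device Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage pipeline for observation streams produced by consumer
    IoT medical devices (blood-pressure monitors and similar vital-sign
    recorders): rule-based validation and cleaning with kNN and decision-tree
    imputation; quantitative data-quality estimation combining operational
    availability, the faulty-data fraction and ICC(2,1) test-retest
    reliability into a weighted keep/discard gate; and structural (bigram
    Dice) plus semantic (precision/recall harmonic mean) schema matching of
    cleaned dataset attributes onto HL7 FHIR resource attributes, with FHIR
    Observation output. Includes a seeded synthetic device-stream generator
    with injectable erroneous, missing and absent records so the whole
    pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
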