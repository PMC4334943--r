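Package: mixsheet
Title: Checklist-Driven Capture and Validation of Metagenomic Sample Metadata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline capture, validation and spreadsheet round-trip of
    GSC MIxS-style metadata for metagenomic sequencing projects. Checklists
    and environmental packages are plain data files; values are stored in an
    entity-attribute-value table; validation runs at two levels (value
    against data type, structure against template) with controlled-vocabulary
    enforcement for ENVO-style biome, feature, material and environmental
    package terms. Workbooks are written and read in XLSX or a diffable
    TSV-per-sheet dialect, and a seeded generator with an error-injection
    ledger provides an exact oracle for the validator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    readxl,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
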