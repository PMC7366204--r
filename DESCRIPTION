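Package: cohortforge
Title: Patient Cohort Identification on an i2b2-Style Star Schema
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained engine for identifying patient cohorts from
    electronic health records. Declarative "Logic" definitions import coded
    observations (diagnoses, laboratory results) into an i2b2-style star
    schema fact store, build hierarchical concept catalogues with local-code
    mappings, compute clinically meaningful derived facts (last value,
    last-n-consecutive comparisons, code-presence flags, script plugins) in
    dependency order, and evaluate boolean cohort query trees (sibling = OR,
    children = AND) that yield per-node attrition counts and flow-diagram
    exports. Includes a deterministic synthetic EHR generator with a planted
    diabetes phenotype and full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
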