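Package: dxdelay
Title: Completeness and Timeliness of Structured EHR Diagnoses Versus
    Computed Phenotypes
Version: 0.1.0
Authors@R:
    person("EHR", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for assessing how completely and how quickly
    structured ICD-9-CM/ICD-10-CM diagnoses are recorded in the electronic
    health record relative to diagnoses computed from vital signs and
    laboratory results, for hypertension, hyperlipidemia, and diabetes
    mellitus. Reads PCORnet-CDM-shaped CSV extracts, detects per-day disease
    signals, applies a two-signals-at-least-30-days-apart rule to date a
    computed diagnosis, matches structured diagnosis codes by ICD parent
    prefix, classifies patients into pre-existing/early/eventual/never
    categories, and estimates time from computed to structured diagnosis
    with a right-censored Kaplan-Meier product-limit estimator. Ships a
    seeded synthetic-data generator with a ground-truth ledger so every
    stage is verifiable without access to protected health information.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
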