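Package: morbrules
Title: Association Rule Mining of Maternal Morbidity in Hospital Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds episodes of care from hospital claim records by
    deterministic record linkage, selects obstetric hospitalizations of
    women aged 10-49, classifies ICD-10 diagnoses into a WHO-adapted
    scheme of twelve maternal morbidity groups, and mines association
    rules (Apriori; support, confidence, lift) linking diagnosis-group
    profiles to in-hospital maternal death. Includes a synthetic claims
    generator with planted relative risks so the full pipeline can be
    exercised and validated without access to the national claims
    databases it emulates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
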