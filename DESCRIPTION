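Package: pvkit
Title: Pharmacovigilance Signal Mining for Spontaneous Reporting Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing spontaneous adverse drug reaction (ADR)
    report databases: ingest and validation of report tables, drug-name and
    ADR-term dictionary normalisation, report-to-event expansion, descriptive
    safety statistics (demographics, severity, system-organ-class and term
    frequencies, outcomes), and disproportionality signal detection with the
    reporting odds ratio (ROR), proportional reporting ratio (PRR), and the
    MHRA composite criterion, including consensus and off-label flagging.
    Ships a configurable synthetic spontaneous-reporting-system generator
    with implantable drug-ADR associations for end-to-end validation and
    operating-characteristic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
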