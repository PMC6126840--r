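Package: partoaudit
Title: Rule-Based Audit of WHO Modified Partographs from Facility Registers
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for auditing how WHO modified partographs are used in
    first-level maternity facilities. Reads intrapartum case records,
    long-format partograph observations and referral registers from CSV;
    reconstructs alert/action-line geometry for each labour; classifies
    partographs against rule-based definitions of foetal distress, prolonged
    labour, obstructed labour and pre-eclampsia; scores charting completeness
    of every partograph component against WHO monitoring intervals and
    compares groups with a pooled two-proportion z-test; links cases to the
    referral register with a partograph-scope filter and assembles a cohort
    flow report. A synthetic labour-cohort simulator with known ground truth
    makes every stage of the pipeline testable without access to facility
    registers.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
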