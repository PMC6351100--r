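Package: cellaudit
Title: Auditing Problematic Cell-Line Usage in Literature Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing the use of misidentified and contaminated
    cell lines in collections of scientific papers. Detects cell-line name
    mentions in methods sections with a dictionary-plus-context recognizer,
    matches detected names against a problematic-cell-line lexicon under
    strict, loose and weighted edit-distance criteria, extracts and resolves
    Research Resource Identifiers (RRIDs) against a local registry snapshot,
    and aggregates results into yearly, journal-level and cohort-comparison
    statistics including pooled two-proportion z-tests. A seeded synthetic
    corpus generator with exact ground truth makes every pipeline stage
    testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
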