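Package: innlint
Title: Orthographic and Stem-Taxonomy Screening of International
    Nonproprietary Names
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing pharmaceutical generic names (International
    Nonproprietary Names, INNs) against WHO naming principles: detection of
    prohibited graphs and digraphs with stem-based exemptions, isolated-element
    and hyphenation checks for multi-word names, word-length statistics,
    matching of names against a hierarchical stem/sub-stem lexicon
    (prefix/suffix/infix/freefix affix classes, allomorphy, position-dependent
    senses), a monoclonal-antibody name grammar, and Levenshtein edit-distance
    screening of name pairs stratified by stem sharing. Includes a synthetic
    name-corpus generator with recorded ground truth so the whole pipeline is
    testable without the WHO name database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
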