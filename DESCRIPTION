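Package: meshprofiler
Title: Journal Specialty Profiling from MeSH Metaterm Categorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Categorizes MEDLINE-indexed articles into medical specialties
    ("metaterms") from their major MeSH descriptor/qualifier pairs, using a
    semantic-link table closed over the MeSH tree-number hierarchy. Builds
    per-journal, per-year specialty profiles (occurrence counts, relative
    weights, dense rankings), cross-journal top-N overlap summaries, and
    inter-year trend reports. Ships readers for the MEDLINE field-tag
    dialect and PubMed XML, a tabular MeSH thesaurus dialect, and a
    synthetic-corpus generator with analytically known specialty mixtures
    so that every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
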