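Package: primerkit
Title: Toolkit for PCR Primer Design and In Silico Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A modular toolkit for designing and evaluating PCR primers,
    including long and chimeric primers. Provides nearest-neighbor and
    Wallace-rule annealing-temperature calculation behind a single
    extensible interface, rule-based 3'-tail scoring of hairpin and
    primer-dimer potential, an exhaustive (non-heuristic) mismatch-tolerant
    search for primer binding sites and potential PCR products, exhaustive
    candidate enumeration with sequence filters, prioritised stable sorting
    and sigmoid-weighted multi-objective ranking of candidates, a
    microsatellite (SSR) detection and flanking-primer pipeline, and a
    command-line front end with text, HTML and CSV reports. Seeded
    synthetic-data generators provide ground-truth fixtures for testing.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    BiocGenerics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
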