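Package: clonalholes
Title: Clonotype-Level Analysis of TCR-Alpha Repertoire Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing T cell receptor alpha-chain repertoires across
    experimental conditions: aggregation of UMI-annotated rearrangement reads
    into clonotype abundance tables, Hill-number diversity with Monte-Carlo
    rarefaction and Good-Turing sample coverage, Morisita-Horn repertoire
    overlap, recurrence-based classification of condition-dependent, shared and
    newcomer clonotypes, natural CD5 subrepertoire classification and
    cross-assignment, paired single-cell clonotype aggregation and public-clone
    detection, V-J junction-editing and gene-position statistics, and a seeded
    synthetic repertoire generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
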