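Package: motifCompartments
Title: Subcellular Localization Assignment and Enrichment Analysis for
    Protein Sequence Motifs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns subcellular localizations to protein sequence motifs by
    combining Swiss-Prot keyword annotation with curated PROSITE true- and
    false-positive hit lists. Maps localization keywords to a controlled
    compartment vocabulary, tests each motif's true-positive and
    false-positive sequence sets for compartment enrichment with an
    upper-tail hypergeometric test, compares the two sets with an exact
    Freeman-Halton Fisher test for 2xc contingency tables (with a
    Monte Carlo fallback for large tables), and summarizes compartment
    co-occurrence and false-positive keyword structure. Includes a
    deterministic synthetic flat-file generator with a ground-truth ledger
    for validation, and a pipeline driver that emits per-motif report
    tables, protein-localization mappings and summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
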