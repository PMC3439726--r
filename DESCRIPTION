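Package: cellviews
Title: Cellular Map, Pathway Treemap, and Gene Ontology Views of Transcriptomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch visualization and over-representation analysis for bulk and
    single-cell transcriptomic measurements. Maps an expression matrix onto
    three biological views rendered as deterministic SVG: a subcellular map of
    a plant cell, a compartment-by-pathway treemap with one-sided Fisher exact
    over-representation tests against a genome background, and Gene Ontology
    hierarchy treemaps (biological process and molecular function) with
    true-path annotation propagation. Supports single-sample display and
    two-sample comparisons (difference, fold change, difference fold), a
    YlOrRd value-to-color scale with automatic or user-set range, and
    automatic chunking of entities into icons so that every compartment can
    display all of its entities. Includes a seeded synthetic-fixture
    generator so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
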