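Package: volcanaut
Title: Headless Exploration of Differential Proteomics and PTM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with processed mass-spectrometry proteomics
    and posttranslational-modification (PTM) tables outside the browser:
    import differential-expression and quantification tables from
    search-engine output using explicit column maps, classify features in
    volcano space, manage selection sets, compute per-sample QC statistics
    (profile plots, sample-sample correlation), harmonize PTM site reports
    from four search-engine dialects into one canonical site table, remap
    PTM residue numbers onto canonical isoforms by global sequence
    alignment, compare experimental sites against reference PTM databases,
    extract motif windows, and persist whole analyses as round-trippable
    JSON session documents. A synthetic-data generator produces every
    supported input dialect with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    methods,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
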