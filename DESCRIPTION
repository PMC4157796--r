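Package: srnadeg
Title: Small RNA and Degradome Sequencing Analysis for Two-Library Plant
    miRNA Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-usable pipeline for plant microRNA discovery from paired
    small-RNA and degradome (PARE) sequencing libraries of two genotypes:
    read cleaning and collapsing to unique 18-30 nt tags, annotation against
    structural ncRNA and mature miRNA references, hairpin-based novel miRNA
    discovery with miRNA* (star) evidence, exact two-library tag-count
    differential expression (reads-per-million normalisation, floored log2
    fold-changes and the Audic-Claverie conditional test), and
    degradome-guided cleavage-target calling with t-plot category
    classification. Includes a fully specified synthetic data generator with
    a machine-readable truth table, so every stage is testable offline, and a
    bundled transcription of a published two-genotype miRNA count table used
    as an exact reproduction surface for the statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
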