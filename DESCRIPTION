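Package: mitoforms
Title: Structural Isoform Analysis of Recombining Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resolves the structural isoform repertoire of recombining plant
    mitochondrial genomes from long reads and paired short reads. Implements
    reverse read mapping of tiling fragments onto long reads, copy-number and
    junction stoichiometry from breakpoint analysis of alignment lengths,
    secondary-building-block extraction and triple-constrained enumeration of
    circular genome arrangements, draft-anchored junction consensus and
    short-read polishing, detection of minor recombinant isoforms from
    mate-pair and Hi-C two-dimensional distance matrices, and near-identical
    repeat discovery. Includes a synthetic-genome simulator (multi-isoform
    circular genomes, long reads, mate pairs, Hi-C ligation chimeras) with
    full ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    graphics,
    grDevices,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
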