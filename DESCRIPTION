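Package: microcensus
Title: Census-Based Taxonomic Profiling of Metagenomes by Read Subsampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the taxonomic composition of a metagenomic short-read
    sample by repeatedly drawing small random subsamples of reads, mapping each
    subsample to a reference collection with a best-hit aligner, projecting hits
    onto a taxonomy tree at a chosen depth, and filtering clades that are not
    observed in a required fraction of iterations. Reports abundance estimates
    with across-iteration uncertainty, provides the exact binomial design
    calculator (detection power, estimation error, subsample-size
    recommendation) that justifies parameter choices, a seed-reproducible
    random read picker for use with other pipelines, an optional host-read
    depletion pre-filter for clinical samples, and a synthetic-community
    generator for hermetic testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'seqio.R'
    'aligner.R'
    'taxonomy.R'
    'census.R'
    'synthdata.R'
    'design.R'
    'cli.R'
    'microcensus-package.R'
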