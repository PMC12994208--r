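Package: sedaTaph
Title: Taphonomy-Aware Analysis of Sedimentary Ancient DNA Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for taxonomic profiling of sedimentary ancient DNA
    (sedaDNA) cores: read-count confidence scoring and negative-control
    filtering, co-occurrence plant-guild construction via classical
    multidimensional scaling and hypercube clustering, guild-profile
    distances, Beta-overlap stratification tests, diffusion-rate bounds,
    a Monte-Carlo-fitted sediment-influx depositional model with
    secure/insecure sample classification, Simpson-index biodiversity
    time series, clade-support SNP counting on gap-concatenated
    multi-taxon alignments, and a seeded synthetic-landscape generator
    with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
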