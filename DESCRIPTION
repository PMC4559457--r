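Package: concatmap
Title: Transgene Concatemer Integration Mapping from Short-Read Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers single-site transgene concatemer integration events from
    paired-end whole-genome sequencing. Simulates diploid genomes carrying a
    head-to-tail concatemer insertion with known ground truth, performs local
    seed-and-extend read mapping with soft clipping against a concatenated
    host-plus-transgene reference, refines the transgene model from pileups,
    calls split-read fusions by soft-clip clustering and clip realignment,
    reconstructs the insertion allele (entry/exit breakpoints, target-site
    duplication, orientation, terminal truncations), estimates concatemer copy
    number from read depth and junction support, and genotypes progeny by
    junction-spanning in-silico PCR with Mendelian segregation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
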