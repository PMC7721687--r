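Package: lahelper
Title: Genome Characterization of dsRNA LA Helper Viruses from Killer Yeasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Annotation and comparative analysis of ~4.6 kb double-stranded
    RNA LA helper-virus genomes of killer yeasts. Partitions sequenced cDNA
    into 5'-extra, canonical and 3'-extra zones under the signed coordinate
    convention used for these genomes; annotates the Gag open reading frame,
    the -1 programmed ribosomal frameshift slippery heptamer, the Pol frame
    and the Gag-Pol fusion protein; discovers the frameshift, packaging and
    replication stem-loop cis-signals by hairpin-restricted nearest-neighbor
    minimum-free-energy folding; characterizes extra sequences (viral
    self-identity, stretches shared between viruses, near-palindromes,
    kissing-loop complexes, host-sequence matches); and builds
    region-resolved percent-identity matrices with neighbor-joining
    phylograms. Includes a synthetic-genome simulator with planted ground
    truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ape,
    jsonlite,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
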