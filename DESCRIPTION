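Package: isoasm
Title: De Novo Assembly of Multi-Isoform Transcriptomes from Short Reads
Version: 0.1.0
Authors@R:
    person("Sam", "Reilly", email = "sam.reilly@example.org",
           role = c("aut", "cre"))
Description: A six-stage de novo assembler for transcriptomes harbouring
    extensive isoform variation, such as snake venom gland transcriptomes.
    Reads are partitioned into protein-family-level groups by windowed
    seed expansion, assembled greedily into approximate guide sequences,
    mapped back onto the guides with a k-mer vote index to form scaffold
    alignments, converted into windowed isoform networks whose nodes are
    hamming-clustered read fragments, and traversed under a physical
    read-linkage (triplet) constraint that suppresses chimeric paths.
    Relative expression is estimated per transcript by length-normalised
    remapping. Includes a paired-end read simulator with a substitution
    error model and evaluation utilities (similarity match networks,
    chimera detection, length distributions) for benchmarking assemblies
    against known reference transcripts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
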