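Package: kmerlock
Title: Privacy-Preserving SNP Panel Genotyping with Encrypted K-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running a secure SNP panel assay in which a patient's
    targeted-sequencing reads are chunked into K-mers, encoded as encrypted
    indicator vectors, and genotyped on the hospital side by a homomorphic
    equality-test protocol, so that neither the raw reads nor the panel content
    is revealed to the other party. Includes panel preprocessing (overlap merge
    and discard), design of the minimum K-mer length under a Point Deviation
    Tolerance (PDT) distinctness criterion, a lattice (RLWE) homomorphic
    encryption backend with slot batching and rotations plus an exact plaintext
    reference backend, a false-negative risk model based on pairwise mutation
    proximity, and a deterministic targeted short-read simulator for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
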