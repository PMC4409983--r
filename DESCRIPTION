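Package: lncevo
Title: Discovery and Comparative Conservation Analysis of Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Pipeline", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for identifying long non-coding RNAs
    (lncRNAs) from dual-assembler transcript calls against a reference
    annotation, classifying transcripts as protein-coding or non-coding with
    a phylogenetic codon-model likelihood-ratio score, quantifying per-gene
    sequence conservation across a species tree with a rate-scaling
    likelihood-ratio test, screening candidate lncRNAs for conserved RNA
    secondary structures, and comparing divergence rates of conserved
    regions versus conserved structures. Includes seeded generators for a
    fully synthetic study (genome, assembler calls, multi-species
    alignments, species tree) with recorded ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
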