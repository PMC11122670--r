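Package: circlocus
Title: Characterization Toolkit for Circular RNA Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational characterization of a circRNA-producing gene
    locus: detection and ranking of reverse complementary matches (RCMs)
    between the introns flanking a backspliced exon block, splice-acceptor
    dispensability analysis for circRNA-specific knockout design, cryptic
    splice-acceptor prediction after acceptor mutagenesis, RFLP genotyping
    fragment prediction, backsplice-junction-centric shRNA and divergent
    primer design, junction-spanning circular ORF discovery, in-silico
    trypsin digestion with discriminative-peptide selection and PRM
    inclusion-list m/z computation, and relative qPCR quantification
    against paired housekeeping genes. Includes a deterministic synthetic
    locus generator so every stage can be exercised end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
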