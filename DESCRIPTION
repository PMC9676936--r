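Package: homeoplex
Title: Homoeolog-Resolved Analysis of Multiplexed Long-Amplicon Nanopore Sequencing
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of barcoded long-amplicon single-molecule
    sequencing of homoeologous gene copies in polyploids, modelled on the three
    VRN1 vernalization-gene homoeologs of hexaploid wheat. Provides a synthetic
    read generator with known ground truth (homoeolog references, planted allele
    edits, copy-number configurations, ONT-like error and chimera models),
    barcode demultiplexing with chimera detection, an SV-tolerant seed-chain
    aligner for homoeolog assignment, reference-guided consensus building,
    structural-variant and SNP/small-indel calling with minor-count, quality and
    homopolymer filters, read-backed haplotype phasing with allele-dosage
    copy-number classification, cultivar grouping, G-quadruplex (QGRS) motif
    scanning, and group-wise trait association (Tukey HSD, Wilcoxon, t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
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
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
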