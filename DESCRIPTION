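Package: iresfinder
Title: Prediction of Cellular Internal Ribosome Entry Sites in Fungal 5'-UTRs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete pipeline for the computational prediction of
    unstructured, A-rich cellular internal ribosome entry sites (IRESs) in
    the 60 nucleotides immediately upstream of fungal translation start
    codons. Extracts strand-aware upstream and negative-control windows
    from genome FASTA plus annotation, computes 29 sequence, folding-energy
    and orthologous-group dispersion features, balances the extreme class
    imbalance with SMOTE oversampling, trains a degree-2 polynomial-kernel
    support vector machine with asymmetric class costs and Platt posterior
    calibration, ranks predictions by combining posteriors with
    orthologous-group Fisher enrichment, and characterizes predicted gene
    sets on protein-protein interaction networks via density null models
    and Louvain module detection. Includes a synthetic multi-organism
    genome generator so every stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    igraph,
    jsonlite,
    MASS,
    rtracklayer,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
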