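Package: pepspace
Title: Exhaustive Proteogenomic Search-Space Construction for Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds exhaustive and RNA-seq-informed peptide search spaces for
    mass-spectrometry-based proteomics and HLA class I immunopeptidomics.
    Constructs noncanonical open-reading-frame strata (CDS main and off-frame,
    5'/3'-UTR, intron, intergenic, lncRNA) from a genome and GTF annotation,
    generates tryptic, nonspecific and proteasome-spliced (forward/reverse cis,
    trans) peptides with origin coordinates, counts splicing events in closed
    form with enumeration oracles, expands fixed and variable
    post-translational modifications with monoisotopic masses, pre-filters
    candidate peptides against observed precursor masses and a calibrated
    additive retention-time model plus a pluggable HLA-binding predictor,
    and provides decoy-symmetric target-decoy FDR post-processing and
    peptide multimapping analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    data.table,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    arrow,
    jsonlite,
    optparse
Config/testthat/edition: 3
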