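Package: prfscan
Title: Prediction of Programmed Ribosomal Frameshift Sites in Prokaryotic
    and Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate programmed ribosomal frameshift (PRF) sites in
    annotated genomes. Overlap regions between consecutive same-strand genes
    are scanned for slippery-sequence motifs; each candidate site is described
    by eleven translation-related signals (frameshift direction, two ribosome
    binding site scores, motif class, A-site codon usage in both frames,
    normalized minimum free energy of downstream RNA windows, and distance to
    the in-frame stop codon) and classified as a backward (-1), forward (+1),
    or non-frameshifting site with a gradient-boosted tree model. Includes
    GenBank flat-file input/output, training from join-annotated genomes,
    MinHash-based taxon-aware leave-one-out validation, and a synthetic genome
    generator with planted frameshift genes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
SystemRequirements: ViennaRNA (RNAfold executable on PATH) for RNA
    minimum-free-energy features
Config/testthat/edition: 3
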