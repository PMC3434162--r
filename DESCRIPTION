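Package: hairpinCRF
Title: Conditional Random Field Scanner for Conserved miRNA Precursor
    Hairpins and Mature 5' Ends
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects evolutionarily conserved microRNA precursor hairpins
    in genomic sequence and pinpoints the 5' end of the mature miRNA.
    Every genomic position is encoded as a 7-dimensional feature vector
    (PhastCons-like and PhyloP-like conservation, base-pair potential and
    base-pair distance from a windowed McCaskill partition function, and
    nucleotide identity), discretized into symbols, and decoded with a
    conditional random field whose sub-models correspond to the anatomical
    parts of a hairpin (flanking regions, mature strand, terminal loop,
    passenger strand). Includes label-constrained likelihood training with
    a Gaussian prior, posterior decoding with segment and 5'-end calling,
    a synthetic-genome generator for validation, and an evaluation
    harness with cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
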