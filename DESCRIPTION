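Package: mapkcascade
Title: Genome-Wide Mining, Duplication and Expression Analysis of MAPK Cascade Gene Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide identification and characterization of the
    three-tier mitogen-activated protein kinase (MAPK) signalling families
    (MAPK, MAPKK, MAPKKK) in a plant genome. Implements the degenerate
    motif grammar that defines each family (TEY/TDY activation loops,
    MAPKK catalytic and active sites, MEKK/RAF/ZIK subfamily signatures),
    reference-panel identity screening, molecular weight and isoelectric
    point calculation, global pairwise and progressive protein alignment,
    neighbor-joining phylogenies with bootstrap, duplicate gene pair
    detection with tandem classification and Nei-Gojobori (1986) Ka/Ks
    estimation, promoter cis-element scanning against an editable element
    dictionary, FPKM/TPM normalization with tag-count differential
    expression testing, and qRT-PCR analysis by the 2^-delta-delta-Ct
    method. A fully parameterized synthetic-corpus generator plants a
    miniature study (proteome, genome with gene models and promoters,
    anchor table, count matrices, Ct tables) with a hidden truth table so
    the complete pipeline can be exercised and verified without external
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
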