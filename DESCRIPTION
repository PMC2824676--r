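Package: RepeatJunctions
Title: Competitive Repeat Annotation and Repeat-Junction Marker Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates multi-source homology evidence (NCBI/WU-style BLAST
    tabular output, cross_match alignments, MUMmer-style exact-match
    coordinates or a built-in maximal exact match finder) over repeat-rich
    genomic sequence such as plant centromeres. Overlapping annotations from
    different repeat databases are competed so that a single best-fitting
    repeat class is reported per locus; class-change boundaries (repeat
    junctions) are detected and paired into single-copy PCR marker
    candidates; paired long terminal repeats are identified from exact-match
    structure and dated with the Kimura two-parameter distance. A
    renderer-independent display model (ruler with assembly-gap bars,
    per-nucleotide coverage charts on two y-axes, masked boxes, HSP arrows,
    leveled exact-match lines) is serialized to SVG and PostScript. A
    synthetic-centromere simulator with full ground truth (tandem satellite
    arrays, nested retroelement insertions, read placements) makes every
    stage testable without external binaries or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    xml2
biocViews: Annotation, Alignment, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
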