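Package: viewcall
Title: Viewpoint-Based Interaction Calling for 3C-seq and 4C-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of long-range chromatin interactions from
    viewpoint-anchored chromosome conformation capture sequencing (3C-seq /
    4C-seq) experiments. Provides in-silico restriction digestion of a
    reference genome, read counting per restriction fragment or genomic
    window with an informative-read filter, power-law reverse-cumulative
    read-count normalization, statistical calling of cis interactions
    against a smoothing-spline distance-decay background and of trans
    interactions against the global signal distribution, q-value false
    discovery rate control with bootstrap pi0 estimation, replicate
    combination via Fisher's method, gene annotation of significant calls,
    bedGraph and text export, domainogram matrices, and a synthetic 3C-seq
    data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
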