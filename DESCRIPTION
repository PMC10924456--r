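Package: oligoSOM
Title: Genome Signatures from Oligonucleotide Composition with Batch-Learning Self-Organizing Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free analysis of genome signatures: fragments genome
    assemblies into fixed-size windows, computes strand-merged (degenerate)
    oligonucleotide composition vectors, clusters them with a deterministic
    batch-learning self-organizing map (PCA-plane initialization, Euclidean
    best-matching-unit assignment), and derives map-level diagnostics
    (species territories, U-matrix, per-oligonucleotide heatmaps).
    Includes dinucleotide statistics (G+C%, CG odds ratio, CG/GC ratio,
    Tukey box-plot summaries), chromosomal window scans for dinucleotide and
    motif enrichment, and a Markov-chain synthetic genome generator for
    end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
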