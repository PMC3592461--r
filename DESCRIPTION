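Package: lncArray
Title: Custom lncRNA Annotation and Exon-Level Expression Analysis for Exon Arrays
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a custom exon-array annotation for long non-coding RNAs
    (lncRNAs): probes are re-mapped to the genome by exact unique matching,
    probes hybridising to protein-coding exons are excluded, overlapping
    same-strand lncRNAs are combined into transcript clusters, and probe sets
    are defined as maximal exonic segments uninterrupted by any member's exon
    boundaries. Transcript clusters are classified by their position relative
    to protein-coding genes (sense, antisense, intronic, bidirectional,
    extension, close, intergenic). On top of the annotation the package
    computes gene-level and exon-level differential expression from
    probe-intensity matrices: quantile normalisation, median-polish
    summarisation, gene-level normalised intensities (GNI) and the Splice
    Index (SI) with Welch t-tests and Benjamini-Hochberg correction. Seeded
    generators for toy genomes, transcriptomes, probe tables and intensity
    matrices with known ground truth are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    limma
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
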