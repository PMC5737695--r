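Package: clipscape
Title: CLIP-Seq Binding Clusters, Crosslink-Deletion Motifs and Last-Exon
    Usage Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a CLIP-seq analysis stack for
    mapping protein-RNA binding: priority-based read categorization into RNA
    classes, 50-bp window RPKM enrichment and binding-cluster calling against
    an RNA-seq input, crosslink-induced deletion site identification with
    ZOOPS k-mer motif enrichment (per-replicate Fisher exact tests combined
    by Fisher's method), strand-oriented metagene and coverage-ratio
    profiles around genomic anchors, exon-exon versus exon-intron
    junction-spanning read statistics, and last-exon differential-expression
    enrichment from exonic-part tables. Includes a deterministic synthetic
    genome and aligned-read simulator with planted ground truth so that the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    GenomicAlignments,
    Rsamtools,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
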