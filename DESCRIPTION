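Package: isopanel
Title: Splice-Isoform Discrimination Panels from In Silico RT-PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discriminating whole-exon-skipping splice isoforms by
    conventional RT-PCR. Builds exon-level gene models from GFF3/GTF and FASTA
    or from a compact isoform table, predicts PCR amplicons on spliced
    transcripts (junction-aware, multi-site), partitions isoforms into gel
    co-migration classes per primer pair, combines primer pairs by partition
    refinement to design minimal diagnostic panels, decodes observed gel band
    patterns back to the isoform sets that explain them, and searches for
    isoform-specific nucleotide or peptide targets (siRNA sites, epitopes)
    including the novel junction k-mers created by exon skipping. Ships a
    synthetic gene generator and an idealized model of the 23-exon human
    periostin (POSTN) gene with its 11 exon-skip isoforms for fully offline
    use.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
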