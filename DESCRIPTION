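Package: ampliSplice
Title: Splice-Defect Quantification, Allele Phasing and Mobile-Element
    Insertion Analysis for Targeted Long-Read cDNA Amplicons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyzes targeted long-read cDNA amplicon sequencing of a
    single transcript to characterize splicing defects. Reads are filtered
    by per-read quality (RQ), their exon-junction chains are extracted from
    spliced alignments and classified into isoform categories (exon
    skipping and co-skipping, pseudoexon inclusion, exon truncation or
    elongation, novel-sequence insertion), and event abundances are
    quantified as junction-read percentages. Reads are phased to alleles
    using heterozygous variant markers inside the amplicon, with
    artifact-base reads excluded from denominators, and allelic depletion
    is flagged. Novel-sequence insertions (e.g. partial SVA retrotransposon
    inclusions) are consensus-assembled, identified against a mobile-element
    library by local alignment, decomposed into breakpoint segments at the
    genomic level, and scanned for candidate splice-donor motifs. A
    synthetic read generator with truth tables makes every stage testable
    without subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    optparse,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
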