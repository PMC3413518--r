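Package: grasstruct
Title: Gene Structure Evolution and Expression Analysis for Grass Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for small grass gene families such as
    the phytoene synthase (PSY) genes. Rebuilds pairwise alignments from
    tabular BLAST HSPs and scores them with cumulative identity (CIP) and
    cumulative alignment length (CALP) statistics to classify orthologs as
    conserved (COS), tandem-duplicated (CNV) or absent (PAV); infers
    exon-intron structure by spliced alignment of a CDS onto genomic sequence
    with intron phase and splice-site annotation; maps intron positions across
    orthologs and infers lineage-specific intron losses and exon fusions by
    Dollo parsimony on a species tree; scans loss breakpoints for short direct
    and inverted repeats, detects MITE-like terminal-inverted-repeat elements,
    downstream exon duplications and ABA-related promoter cis-elements; and
    performs efficiency-normalized relative quantification of qPCR Cq tables
    with reference-gene normalization, fold changes and one-way ANOVA. A
    seeded synthetic-data generator emulates multi-species ortholog families
    with planted intron losses, homoeologous copies and Cq tables with known
    fold changes, providing ground truth for every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
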