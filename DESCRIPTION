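Package: chimeRclip
Title: Simulation and Analysis of Chimeric eCLIP miRNA Target Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for chimeric eCLIP
    (miR-eCLIP) data: simulation of UMI-bearing IP and size-matched input
    libraries with planted AGO2 binding signal and a machine-readable truth
    table; UMI extraction and 3' adapter trimming; repeat filtering and
    seeded ungapped read mapping against a toy genome; chimeric read
    deconvolution by reverse-mapping mature miRNA sequences; UMI-based PCR
    deduplication; strand-aware cluster calling with IP-versus-input
    enrichment scoring (RPM, log2 fold change, one-sided exact test) and
    reproducibility filtering; genomic feature annotation under a fixed
    priority hierarchy; miRNA seed-family summaries; candidate-gene
    prioritization combining 3' UTR chimeric peak counts with differential
    expression; and qPCR arithmetic (2^-ddCt relative expression and exon
    inclusion:skipping ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
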