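Package: chromquant
Title: Quantification of ChIP-seq, MNase-seq and Bisulfite Methylome Data
    in Compact Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for multi-assay chromatin studies in compact
    genomes with a mitochondrial contig, such as Neurospora crassa.
    Implements mitochondrial-median normalization of windowed ChIP-seq
    coverage, expression-stratified TSS/TTS metaplots and heatmaps,
    MNase-seq fragment-size statistics and nucleosome-edge profiles, and
    whole-genome bisulfite methylome analysis (nonconversion estimation
    from mitochondrial DNA, per-cytosine binomial calling with
    Benjamini-Hochberg correction, weighted methylation levels, shared-site
    comparisons and sliding-window DMR detection). A seeded synthetic-data
    generator produces genomes, annotations, methylated domains and
    simulated ChIP/MNase/bisulfite data with the statistical structure the
    analyses assume, so every stage can be exercised end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
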