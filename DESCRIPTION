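Package: ploidyTE
Title: TE-Stratified H3K27me3 Comparison Between Ploidy Levels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares repressive chromatin (H3K27me3) between a diploid and a
    tetraploid line in the genomic context of transposable elements (TEs).
    Classifies TEs relative to genes by a majority-overlap rule, dissects gene
    bodies and 2 kb flanks into TE and non-TE segments, quantifies ChIP signal
    from paired-end fragment midpoints with interval-length, sequencing-depth
    and IgG normalization, runs paired Wilcoxon signed-rank comparisons
    stratified by TE superfamily, and links chromatin differences to the
    expression of TE-cognate genes. Ships a synthetic-data generator with
    planted enrichment structure so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
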