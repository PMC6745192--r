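Package: atbias
Title: Composition-Bias Diagnostics for AT-Rich Reduced Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extremely AT-rich, reduced organellar
    genomes such as the plastomes of holoparasitic plants. Provides
    windowed and feature-aware AT-content profiling, codon and amino-acid
    usage statistics with composition-null expectations, a closed-form
    stop-codon probability model for AT-biased sequences, an
    alignment-column-removal diagnostic for compositional attraction in
    phylogenetic trees (with neighbor-joining, bootstrap supports and
    low-support collapse), rank-correlation analysis of sequencing depth
    and insert size against window AT content, read- and k-mer-based
    genome-size estimation, and a synthetic-data module that simulates
    alignments under branch-specific HKY models, AT-dependent depth
    tracks and k-mer spectra for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    IRanges,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
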