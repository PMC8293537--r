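Package: poolcnv
Title: Copy-Number Variant Calling for Multiplexed-Capture Exome Pools
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects copy-number variants from read-depth in pools of
    exome libraries captured together in a single multiplexed reaction.
    Per-target molecule counts are modelled with a shared negative
    binomial model whose per-target dispersions are shrunken toward a
    common value; copy states are estimated by iterating size-factor
    normalisation, method-of-moments dispersion estimation and
    maximum-likelihood state assignment over a discrete copy-state grid,
    with diploid p-values adjusted by the Benjamini-Hochberg procedure.
    Includes a multinomial capture simulator with known copy states, a
    maximum-likelihood Dirichlet fit for quantifying inter-sample capture
    variance, fragment counting from paired-end alignments over target
    intervals, and exon-level benchmarking metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
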