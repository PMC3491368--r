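Package: readerscope
Title: Proteogenomic Analysis of Histone-Code Reader Bound Nucleosomes
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies combinatorial histone H3/H4 post-translational
    modifications from bottom-up mass spectrometry of propionylated
    peptides, including non-negative least-squares deconvolution of
    co-eluting isobaric acetyl positional isomers, and maps reader-bound
    nucleosomes from ChIP-seq tags: per-strand deduplication, 75-bp tag
    shifting, window counting with depth normalization and control
    subtraction, Poisson-background island calling, promoter binding and
    combinatorial binding patterns, RPKM expression stratification,
    metagene profiles, and knockdown-response summaries. A synthetic-data
    module generates spectra and reads with known ground truth so every
    stage has parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    mzR,
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
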