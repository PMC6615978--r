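Package: sexchromr
Title: Sex Chromosome Complement Inference and Homology-Aware Remapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers an individual's sex chromosome complement from aligned
    short-read sequencing data and corrects read-mapping artifacts caused by
    X/Y (or Z/W) sequence homology. Builds paired sex-specific reference
    genomes by hard-masking whole chromosomes or BED regions while preserving
    sequence dictionaries; tabulates windowed depth, mapping-quality and
    allele read-balance metrics from BAM and VCF input; compares chromosome
    depth distributions with bootstrap confidence intervals, permutation
    tests and two-sample Kolmogorov-Smirnov tests; and strips, remaps and
    merges sex-chromosome reads against the reference matching the inferred
    complement. A seeded simulator generates toy genomes with
    pseudoautosomal and X-transposed-like regions, alignments of known
    ploidy, and truth variants, so the full pipeline is testable without
    external data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
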