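Package: svkit
Title: Split-Read Structural Variant Calling, Phasing and Rearrangement
    Reconstruction for Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolchain for structural variant (SV) analysis of noisy long
    sequencing reads (e.g. nanopore). Candidate breakpoint junctions are
    extracted from split alignments, canonicalized, clustered and typed into
    genotyped SV calls with breakend-aware VCF output; calls are post-filtered
    against homopolymer and tandem-repeat tracks and by a random-forest model
    over twelve alignment-evidence features. Heterozygous SVs are assigned a
    parental haplotype from phased SNVs using per-read base-quality
    likelihoods, and phase-partitioned alignments are chained into contigs and
    derivative-chromosome layouts to reconstruct complex rearrangements such
    as chromothripsis. A seeded simulator shatters a chromosome, emits
    error-injected reads with oracle split alignments, and scores call sets
    against the simulated truth, including confidence-interval proximity and
    reciprocal-overlap matching between SV call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    methods,
    randomForest,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
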