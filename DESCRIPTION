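Package: gametrace
Title: Gamete Transcript Classes and Sperm Promoter Chromatin States Through
    Development and Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for tracing gamete-derived transcripts and
    the chromatin states of their promoters through mammalian development.
    Classifies transcripts as sperm-specific, oocyte-specific, shared or
    miscellaneous from replicate TPM matrices; builds binned H3K4me3/H3K27me3
    promoter signal matrices and clusters them by k-means into chromatin
    states (high-K4, low-K4, bivalent, K4-K27-); calls zygotic-genome-activation
    and transcript-degradation trajectories across preimplantation stages,
    spermatogenesis and tissue panels; traces persistence of sperm-derived
    chromatin states into germ layers and somatic tissues; provides
    hypergeometric term and PWM motif over-representation; and scores
    tumor-versus-normal deregulation per cancer type. A synthetic data
    generator with planted truth labels makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    cluster,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
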