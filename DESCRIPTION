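Package: trcscape
Title: Directional Transcription-Replication Conflict Analysis from
    R-Loop and Replication-Fork Directionality Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Locates directional transcription-replication conflicts (TRCs)
    by crossing stranded R-loop peaks with OK-seq replication fork
    directionality, screens chromatin and DNA-damage-response factor
    coverage for center-versus-flank enrichment at those sites, and
    quantifies cancer mutagenesis conditioned on conflict orientation:
    mutation density tracks, two-threshold hotspot calling, per-tumor
    R-loop mutation burden by chromatin-remodeler status, SBS96/ID83
    context matrices, Kullback-Leibler non-negative matrix factorization
    of mutational signatures, per-mutation signature assignment and
    region-conditioned risk ratios. A seeded synthetic-genome generator
    with planted effects provides parameter-recovery testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    Matrix,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
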