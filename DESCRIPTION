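Package: cnvrpipe
Title: Overlap-Criterion Merging, Consensus and Novelty Screening for SNP-Array CNV Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing machinery for copy number variant (CNV) calls
    from SNP genotyping arrays. Merges overlapping CNVs into CNV regions
    (CNVRs) under two overlap criteria (any shared base pair, or a shared
    length of at least 40% of the smaller event), intersects call sets from
    multiple detection algorithms into consensus calls, applies the standard
    post-call filters (minimum probe count, minimum size, Log Bayes Factor),
    classifies log R ratio / B-allele frequency segments into homozygous
    deletions, hemizygous deletions and amplifications, screens study calls
    against literature CNV databases through a four-stage novelty flow, and
    summarises call sets by type, size class and per-subject burden. A
    seed-deterministic synthetic-data generator emulates a CNV-enriched
    ~47K-marker autosomal array with implanted events, discordant
    pseudo-algorithm call sets and literature-style reference databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    knitr,
    rmarkdown
Config/testthat/edition: 3
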