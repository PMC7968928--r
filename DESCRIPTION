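Package: nucshift
Title: Nucleosome Dyad Profiling and Remodeler-Targeted Shift Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing targeted nucleosome positioning from
    MNase-seq and ChIP-seq data. Converts paired-end MNase fragments into
    normalized per-base-pair nucleosome dyad tracks, scans genomes for
    degenerate (IUPAC) transcription-factor motifs, builds anchor-centred
    signal matrices, meta-profiles and genotype difference heatmaps with
    k-means clustering, quantifies per-locus nucleosome shifts and
    phasing decay, and calls ChIP enrichment peaks with a sliding-window
    threshold caller including paired-subunit centre-offset analysis. A
    synthetic chromatin generator produces genomes with planted motifs,
    genotype-dependent phased nucleosome arrays, MNase fragments and ChIP
    reads with full ground-truth bookkeeping, so every stage of the
    pipeline can be verified end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
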