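Package: metaprofiler
Title: Amplicon Metabarcoding with Calibrated Per-Rank Identity Thresholds
Version: 0.3.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for marker-gene (tufA-style) amplicon metabarcoding of
    endolithic and other microbial phototroph communities. Covers degenerate
    primer evaluation and in-silico PCR, paired-end read merging,
    demultiplexing, expected-error filtering, dereplication and
    abundance-based denoising, reference-based chimera and contaminant
    screening, dual OTU clustering (greedy global-threshold centroids and
    local d-step agglomeration) with a core-OTU consensus, read mapping and
    community profiling, and - centrally - calibration of per-rank
    conservative (clade-based) and relaxed (best-hit) percent-identity
    thresholds from a taxonomy-annotated reference alignment, used for
    multi-rank taxonomic annotation of OTUs. A synthetic-data module
    generates taxonomy-structured reference databases and error-bearing
    reads so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
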