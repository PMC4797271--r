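Package: comascan
Title: Topology-Aware Detection and Modeling of Dual-Topology
    Transcription-Factor Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying transcription factors that recognize a short
    DNA word in two topologically distinct arrangements, modeled on the
    quorum-sensing activator ComA of Bacillus subtilis: a hexameric
    recognition element (consensus TTGCGG) occurring either as an inverted
    repeat with a 4-nt spacer (the canonical dyad site) or as a direct repeat
    with a 5-nt spacer (the non-canonical tandem site).  Provides a position
    frequency/weight matrix motif model with exact score-tail p-values, a
    both-strand scanner that pairs element matches into inverted- or
    direct-repeat units under stringent (mismatch) or relaxed (p-value)
    criteria, an empirical affinity classifier encoding spacer and
    point-substitution rules measured by electrophoretic mobility shift
    assays, cooperative Hill-binding occupancy and titration-curve fitting,
    a bacterial promoter architecture classifier (class I / II / III /
    cluster-plus-core), and seeded synthetic-data generators so every stage
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
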