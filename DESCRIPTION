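Package: plastoflux
Title: Detection and Dating of Mitochondrial Plastid DNA and Its Impact
    on Plant DNA Barcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying plastid-to-mitochondrial genome flux in
    plants. Detects mitochondrial sequences of plastid origin (MTPTs) by
    seed-and-extend local alignment with identity, length and E-value
    filters and tRNA/rRNA masking; aggregates MTPT segments from many
    species onto a reference plastid backbone as a depth profile with
    gene-frequency classes; estimates synonymous divergence (Ks) between
    homologous coding sequences with the Nei-Gojobori (1986) counting
    method and dates species divergence and plastid-mitochondrial flux
    episodes from compartment-specific molecular clocks; calls plastid
    polymorphisms, applies marker-design filters, predicts PCR amplicons
    in both organelle compartments to flag MTPT co-amplification, and
    estimates organelle copy fractions from read depth; and evaluates
    positive versus negative multi-marker authentication rules. A
    synthetic organelle-genome generator provides fully specified inputs
    so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
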