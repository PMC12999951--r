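Package: repliskew
Title: Nucleotide Skew Decomposition and Replichore Analysis of Prokaryotic Replicons
Version: 0.1.0
Authors@R:
    person("Repliskew", "Developers", email = "repliskew@example.org",
           role = c("aut", "cre"))
Description: Computes windowed and cumulative GC skew on prokaryotic replicons,
    decomposed by codon position and coding status, together with the cumulative
    gene strand bias (GSB) curve, the Skew Index (SkewI) summarising genome-wide
    GC asymmetry, and a two-segment piecewise-linear fit of the cumulative skew
    that estimates the leading-strand fraction ('div') and the origin/terminus of
    replication. Provides per-replicon correlation of GSB against each skew
    component, class-level aggregation, Chargaff parity regression, group
    comparison tests, a batch pipeline with a command-line front-end, and a
    synthetic circular-replicon generator with strand-specific mutational bias
    and codon-position-specific composition for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
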