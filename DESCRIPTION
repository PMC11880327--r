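Package: tcrshape
Title: Structural and Sequence Diversity Analysis of TCR CDR Loops
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of conformational diversity in T-cell
    receptor (TCR) complementarity-determining region (CDR) loops from
    IMGT-numbered variable-domain structures. Provides IMGT-defined loop and
    anchor extraction, anchor-superposed backbone RMSD with cubic-spline
    up-sampling for loops of unequal length, greedy threshold clustering of
    structural and sequence distance matrices, VJ-gene structural coherence,
    sequence identity and per-position composition metrics, per-region
    benchmarking statistics for comparing structure predictors, and a
    synthetic repertoire generator with planted conformational clusters for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
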