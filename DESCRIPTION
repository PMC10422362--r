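Package: qualstrat
Title: Quality-Symbol Stratified Evaluation of Basecalled Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the per-base quality symbols emitted by
    nanopore basecallers. Implements Phred symbol conversions and the
    published Chiron/Causalcall and Flappie/Nanonet quality-score formulas
    with their scaling-coefficient sets; repeat masking of reference genomes
    by N-substitution from BED intervals with masking reports; CIGAR-driven
    stratification of alignment outcomes (matched, mismatched, inserted,
    clipped) by quality symbol; quality-symbol distributions and read-set
    summaries; a three-variant (real / constant '?' / no-quality) invariance
    harness for downstream tools; and a quality-aware read simulator emitting
    ground-truth alignments so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
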