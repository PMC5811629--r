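Package: occutile
Title: Differential RNA Polymerase Occupancy from Two-Color Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of differential RNA polymerase occupancy between two
    bacterial strains measured by two-color (Cy3/Cy5) ChIP-chip tiling
    arrays: per-probe mutant/wild-type ratio computation with optional
    median-ratio normalization, run-based calling of increased- and
    decreased-occupancy peaks with combined-intensity quantification,
    assignment of peaks to open reading frames and cryptic prophage
    intervals, prophage enrichment summaries, overlap of external binding
    site tracks with prophages, and companion delta-delta-Ct relative
    expression analysis of qRT-PCR validation data.  A seeded simulator
    generates genome annotations, two-channel probe intensities with
    planted differential regions, and replicated Ct tables for testing
    and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
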