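Package: gfap4c
Title: Bait-Centric e4C Screening for Genes Co-Associated and Co-Expressed
    with Gfap During Astrocyte Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for bait-centric enhanced circular
    chromosome conformation capture (e4C) screens on two-channel tiling
    microarrays.  Calls reproducible e4C hits from log2 signal/genomic-control
    ratios with a sliding-window smoother and a fixed cut-off, maps peaks to
    genes within a configurable distance, converts expression-array
    intensities to mRNA copies per cell by spike-in (Percellome-style)
    calibration, intersects condition-exclusive association and expression
    sets into a candidate gene table, and scans candidate promoters for
    STAT3 binding motifs with a position weight matrix.  Ships statistics
    for 3D DNA-FISH validation (shortest inter-locus distance association
    calls, residual analysis of chi-squared tests, Fisher's exact test,
    two-sample Kolmogorov-Smirnov, one-way ANOVA) and a synthetic-data
    generator with known ground truth covering every input the pipeline
    consumes: in-silico double restriction digests, probe arrays with
    planted bait contacts, dosed expression spike-ins, and 3D nuclei with a
    planted association fraction.
License: MIT + file LICENSE
Encoding: UTF-8
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
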