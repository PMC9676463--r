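Package: taindex
Title: Translational Attenuation Index and RNA Oxidation Analysis for
    Reactive-Oxygen-Species Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Attributes transcriptomic responses to cytosolic versus plastidic
    origin by scoring differential-expression tables against a reference
    translational-arrest (cycloheximide) transcriptome. Implements the
    Translational Attenuation Index (TAI) with ranked waterfall diagnostics and
    an exact binomial null test, gene-set overlap statistics (Venn region
    counts, overlap percentages, Fisher's exact test), correlation of
    fold-change profiles against panels of ROS-source signatures, a Poisson
    model converting measured 8-oxoguanosine/guanosine ratios into
    per-transcript oxidation loads and translational competence, and a
    synthetic-data generator with known ground truth, including a mechanistic
    oxidation-to-derepression mode, so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
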