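Package: petnorm
Title: Normative W-Score and Partial-Volume-Corrected Analysis of Brain PET
    on Synthetic Phantoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for presymptomatic-cohort style analysis of tracer-uptake
    brain images: Mueller-Gartner and geometric-transfer-matrix partial-volume
    correction, intensity normalization (GM-mask proportional scaling and
    cerebellar SUVR), masked Gaussian smoothing, mass-univariate group
    inference with cluster-level familywise-error control by Freedman-Lane
    permutation, age-normative W-score maps with frequency summaries, atlas
    volume-of-interest statistics with Benjamini-Hochberg correction, and
    clinical and fluid-biomarker statistics (chi-square, Mann-Whitney,
    neurofilament cutoff and cognitive-percentile classification). Because
    study scans are rarely shareable, the package ships a deterministic
    synthetic phantom generator producing template tissue maps, an atlas, and
    cohorts with configurable regional hypo- and hypermetabolism, atrophy and
    clinical covariates, so every stage of the pipeline is testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
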