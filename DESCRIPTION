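Package: stiffnet
Title: Stiffness Network Analysis of Two-Cohort Microbiome Co-Occurrence Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies per-taxon stiffness parameters (force, displacement,
    stiffness scale, impact, stability) on signed weighted co-occurrence
    networks built from two-cohort relative-abundance data, identifies taxa
    with significantly altered stiffness via a pooled-sample permutation null
    with pseudo-P values and false-discovery-rate control, and characterises
    biomarker neighbourhoods (positive/negative edge ratios, first-order
    neighbour clusters, all-positive biomarker subgroups). Includes a
    logistic-normal synthetic-data generator with planted relationship
    alterations for calibration and recovery studies.
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
    igraph,
    jsonlite,
    MASS,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
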