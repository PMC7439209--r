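Package: hemimorph
Title: Intraindividual Hemispheric Morphological Networks from Cortical
    Thickness Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-subject left- and right-hemispheric morphological
    brain networks in which the edge between two cortical subregions is the
    Jensen-Shannon similarity between their kernel-density-estimated cortical
    thickness distributions. Provides parcellation upsampling of 78 anatomical
    regions into 512 similar-size subregions, sparsity-thresholded binary
    network construction, global and nodal graph metrics with
    degree-preserving random-network normalization, sparsity-integrated
    metrics, hemispheric asymmetry indexes for homologous region pairs, and
    the accompanying group statistics (repeated-measures ANOVA with an age
    covariate, one- and two-sample t-tests on asymmetry indexes, and FDR
    control). Includes a synthetic cohort generator that emulates
    surface-extraction output with injectable gender-by-hemisphere effects
    for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
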