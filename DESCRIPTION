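Package: ssrcurate
Title: Curation of SSR Fingerprint Collections in Clonal Genebanks
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating microsatellite (SSR) fingerprint data from
    clonally propagated genebank collections. Harmonizes fragment lengths
    across genotyping batches, groups accessions into molecular groups by
    tolerant fingerprint matching, combines genetic groups with pomological
    determinations into trueness-to-type categories, and computes the standard
    population-genetic summaries used in germplasm characterization: per-locus
    diversity parameters (Na, Ne, Ho, He), rarefied allelic richness,
    probability-of-identity curves and minimal discriminating marker sets,
    pairwise Fst, unweighted neighbor-joining trees with locus-resampling
    bootstrap, and likelihood-based verification of pedigree hypotheses with
    simulation-calibrated confidence thresholds. Includes a fully seeded
    synthetic-collection generator with ground truth so every pipeline stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
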