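Package: aridr
Title: Comparative Drought-Response Transcriptomics and Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for comparative drought-response
    analysis across related plant species. Builds expressed-mutual-ortholog
    (EMO) tables from reciprocal-best-hit orthology over protein similarity
    searches, computes water-deficit fold changes and response-timing
    classifications across a stress time course, tests multi-species overlap
    of regulated gene sets with a permutation null, detects weighted
    co-expression modules via soft-thresholded adjacency, topological
    overlap and dendrogram cutting, associates module eigengenes with sample
    traits, performs term enrichment with Benjamini-Hochberg correction, and
    derives rosette growth and stomatal phenotyping metrics. Includes seeded
    synthetic-data generators with planted ground truth for every input the
    pipeline consumes, and an end-to-end pipeline runner with a
    machine-readable report.
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
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
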