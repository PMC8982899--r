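Package: omusynergy
Title: Network-Based Prioritization of Synergistic Drug Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Converts single-drug transcriptomic responses and single-drug
    dose-response phenotypes into a ranked list of candidate synergistic
    two-drug combinations. Per-condition gene regulatory networks are inferred
    by message passing over a regulatory prior, protein-protein interactions
    and co-expression; drug-induced rewiring is summarized as differential
    gene modules, pooled across drugs into an operational module unit (OMU)
    system, and linked to growth-rate inhibition (GRmax) through an isometric
    log-ratio balance regression. Candidate pairs are scored by a differential
    growth impact score (DGIS) and can be validated against zero-interaction
    potency (ZIP) synergy scores from dose-response matrices, with a
    joint-binomial enrichment statistic. Includes a seeded synthetic-study
    generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
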