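Package: factorex
Title: Factorial Differential Expression and Pathway Interpretation for
    Two-Factor Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for analysing genes-by-samples
    expression matrices from 2x2 factorial designs (for example genotype by
    oxygen exposure in neonatal hyperoxia models of bronchopulmonary
    dysplasia). Provides gene-wise two-way ANOVA with F tests for both main
    effects and their interaction, Fisher's LSD pairwise contrasts with
    signed fold changes, Benjamini-Hochberg false-discovery-rate control,
    partition of significant genes into the seven regions of the
    three-effect Venn diagram, hypergeometric gene-set over-representation
    against GMT collections, collapsing of redundant enriched pathways into
    "mega pathways" by complete-linkage clustering on the Jaccard distance,
    z-scored heatmap export, and validation of array fold changes against
    qPCR via the 2^-ddCt method. Includes a synthetic-data generator with
    planted, recoverable effects so the whole pipeline is testable end to
    end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
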