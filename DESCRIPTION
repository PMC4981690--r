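Package: gh9class
Title: Profile-HMM and Neural-Network Classification of Plant GH9
    Endoglucanases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies plant glycoside hydrolase family 9 (GH9)
    endoglucanases into subclasses A (membrane-anchored), B (secreted)
    and C (secreted with a C-terminal CBM49 module) from profile hidden
    Markov model bit scores. Implements the modified z-score
    disambiguation statistic (alpha/beta), a screening filter on beta and
    the median inter-profile score difference, derivation of
    class-specific beta centroids by one-dimensional k-means, a small
    feed-forward neural network that approximates the centroids from the
    alpha triple, and an interval rule table for final class assignment,
    together with precision/recall evaluation, taxonomic summaries, a
    leave-one-out profile registry, wrappers for HMMER profile building
    and scoring, and seeded generators of class-architectured synthetic
    protein families and score tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: HMMER3 (hmmbuild, hmmsearch); MAFFT (for the
    alignment helper used when building profiles from unaligned
    sequences)
Config/testthat/edition: 3
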