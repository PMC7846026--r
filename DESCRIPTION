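Package: tcrshare
Title: Public TCR CDR3 Clone Sharing Within and Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for T-cell receptor (TCR) CDR3 repertoires aimed
    at tumor-associated public clones. Classifies amino-acid CDR3 sequences as
    private, public-inclusive or public-exclusive across subjects; quantifies
    convergent recombination (the number of distinct nucleotide rearrangements
    encoding one amino-acid CDR3); computes abundance-weighted repertoire
    overlap (Morisita-Horn, weighted Jaccard), a cross-species rank-area
    metric, disease-stage similarity, Levenshtein clone networks, and paired
    single-cell alpha-beta chain matching against bulk repertoires. Ships a
    synthetic repertoire generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    igraph,
    lmtest,
    vegan,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
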