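Package: genedecay
Title: Gene-Decay Analysis: Inactivating-Mutation Screening, Branch-Model
    dN/dS Tests, and Pseudogene Dating on Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying gene loss across a phylogeny from coding
    sequences. Scans orthologous CDS for inactivating lesions (start-codon
    loss, premature stops, frameshift indels, splice-site disruptions,
    stop-codon loss), places shared lesions on ancestral branches by Dollo
    parsimony, fits GY94-style codon substitution models with branch-specific
    dN/dS (omega) and nested likelihood-ratio tests for relaxed selection,
    estimates a selection-intensity exponent K for relaxation, and dates gene
    inactivation on pseudogenized branches with a two-period (functional then
    neutral) model. A truth-labelled synthetic-data generator makes the whole
    pipeline testable offline. Results are returned as tibbles and fitted
    objects carry broom-style tidy() and glance() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
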