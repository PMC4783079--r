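Package: drsig
Title: Signature-Based In Silico Drug Repositioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-repositioning candidates from binary compound
    signatures: structural fingerprints (S), target gene sets (T) and
    drug-induced expression signatures (E). Compound-disease association
    features are built as mean Tanimoto similarities against known-drug and
    disease signature pools, combined by seven logistic classifiers (S, T,
    E, ST, SE, TE, STE) into a DR score in [0, 1], and evaluated by
    repeated stratified cross-validation and against high-throughput
    screening hit lists split into anti-cancer and novel categories.
    Mode-of-action profiling applies hypergeometric pathway enrichment to
    up/down gene sets, aggregates per-cell-context p-values by harmonic
    mean, adjusts by Benjamini-Hochberg, and clusters drugs by cosine
    distance of -log10 p profiles. A synthetic-world generator with
    switchable signal channels makes every stage testable without external
    data.
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
    Matrix,
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
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
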