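Package: idrmut
Title: Disorder-Centric Analysis of Missense Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the impact of single amino-acid
    substitutions on intrinsic protein disorder. Scores wild-type and
    point-mutated sequences with a sliding-window disorder propensity
    predictor, classifies mutations by order/disorder transition at the
    mutated residue, scans disorder profiles for alpha-MoRF candidate
    regions and calls per-mutation MoRF gain/loss, curates mutation
    datasets (redundancy clustering, outlier removal, neutral
    evolutionary substitution controls from ortholog alignments), and
    computes enrichment statistics: Fisher exact tests with Bonferroni
    correction, fold differences with standard errors, residue
    composition profiling, substitution transition matrices, and
    functional-feature enrichment. Includes a synthetic-data generator
    that plants known transition probabilities and annotation
    enrichments so every pipeline stage can be validated against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
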