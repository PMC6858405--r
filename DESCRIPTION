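Package: accumrate
Title: Variation in Bacterial Mutation-Accumulation Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of why the rate at which bacteria accumulate mutations
    over historical timescales varies across species. Provides a Wright-Fisher
    transition-matrix model of the decline in the accumulation rate caused by
    purifying selection under a gamma distribution of fitness effects;
    curation and aggregation of literature-style per-estimate rate tables;
    Nei-Gojobori piN/piS nucleotide diversity from codon alignments;
    phylogenetic comparative methods (independent contrasts, Pagel's lambda,
    Blomberg's K, sister-pair tests); the classical statistics of the
    comparative analysis (correlations, common-slope ANCOVA, standardized
    multiple regression, correlation power analysis); and seeded generators
    for synthetic trees, traits, rate tables and codon alignments so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    phytools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
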