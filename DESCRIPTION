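Package: polokit
Title: Expression Breadth, Lineage Divergence, and Sex-Chromosome
    Transmission Analysis for Testis-Specialized Gene Duplicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the evolution and function of
    testis-specialized gene duplicates such as the Drosophila
    pseudoobscura polo-like kinase paralog. Computes the tau
    tissue-specificity index from normalized read-count expression
    tables, assigns amino-acid substitutions to lineages by outgroup
    parsimony and applies Tajima's one-degree-of-freedom relative-rate
    test (overall and per protein domain), builds McDonald-Kreitman
    2x2 tables from in-frame multi-strain codon alignments with
    Nei-Gojobori-style pathway counting and an exact test, formalizes
    a meiosis-II sex-chromosome nondisjunction model mapping sperm and
    zygote viability classes to expected brood sex ratios, and fits
    the mixed-effects progeny-count, siring, and sex-ratio models used
    in transgene fertility assays. A synthetic-data generator plants
    known substitution counts, polymorphism tables, expression
    profiles, and brood structures so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    nlme,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, Sequencing, GeneExpression, StatisticalMethod
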