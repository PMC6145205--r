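Package: gfqmdr
Type: Package
Title: Generalized Fuzzy Multifactor Dimensionality Reduction for
    Quantitative Traits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects m-way gene-gene interactions (epistasis) associated with
    a quantitative trait. The trait is discretized into J ordinal levels and
    every candidate set of markers is scored as a multi-locus genotype
    classifier using a generalized fuzzy balanced accuracy whose membership
    functions have an extended range of [-1, 1], so that trait values far
    from a level count against it. Includes the traditional-membership
    (FQMDR), Kendall tau-b (OMDR) and crisp balanced-accuracy (MDR) baseline
    scorers, cross-validated exhaustive search with generalized
    cross-validation consistency, permutation p-values, a Hardy-Weinberg
    penetrance-grid simulation suite, and replicate-level hit-ratio and
    type-I-error experiment runners.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    VariantAnnotation
biocViews: SNP, GeneticVariability, GenomeWideAssociation, Epistasis,
    Classification
Config/testthat/edition: 3
RoxygenNote: 7.3.3
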