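Package: longidecomp
Title: Decomposing Longitudinal Whole-Blood Expression Changes into
    Cell-Composition and Transcriptional-Regulation Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for longitudinal bulk RNA-seq studies with repeated
    measures per subject, built around the question of whether expression
    changes over time reflect shifts in blood cell-type composition or
    transcriptional regulation. Provides a synthetic-cohort generator with
    known ground truth (cell-type signature mixtures, time-varying
    composition, planted multiplicative regulation effects), gene filtering
    and trimmed-mean-of-M-values (TMM) normalization, nonnegative
    least-squares deconvolution against a signature matrix with principal
    component summaries of the estimated proportions, per-gene negative
    binomial generalized estimating equations (GEE) with robust sandwich
    variance and joint Wald tests, fold-change based calling of
    time-associated genes with mechanism classification from paired
    adjusted/unadjusted screens, hypergeometric gene-set enrichment over
    GMT collections, and weighted co-expression module detection (biweight
    midcorrelation, signed-hybrid adjacency, topological overlap, eigengene
    merging).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    edgeR
Config/testthat/edition: 3
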