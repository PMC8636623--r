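Package: immunoedit
Title: Immune-Selection Mutation Profiling and Pooled CRISPR Screen
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for profiling somatic mutations enriched by host T cell
    selection in syngeneic tumor cohorts and for analysing targeted pooled
    CRISPR knockout screens of the candidate genes. Implements allele-
    frequency based cross-cohort hotspot filtering with classification of
    candidates into PD-1-dependent and PD-1-independent immune-evasion
    categories, library-size normalization with a pseudo-count, conditional
    negative-binomial exact testing of sgRNA abundance, modified robust rank
    aggregation (alpha-RRA) with permutation p-values, hit calling at
    fold-change and p-value cut-offs, cytotoxic T cell infiltration scoring
    and pan-cohort Spearman association summaries, plus a synthetic
    clonal-evolution and screen-count generator with ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'immunoedit-package.R'
    'infiltration.R'
    'io.R'
    'methods.R'
    'screen-analysis.R'
    'simulate.R'
    'utils.R'
    'variant-profiling.R'
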