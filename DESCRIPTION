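Package: splicecode
Title: Splicing-Code Prediction and Regulatory Analysis of Cassette Exons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a cassette exon is alternatively spliced and
    whether its inclusion changes between tissue groups, from regulatory
    features extracted around an exon triplet (motif occurrences in seven
    regions, splice-site strengths, first-upstream-AG distance, lengths,
    nucleotide composition, nucleosome-occupancy summaries). Predictions come
    from a two-stage ensemble of sparse Bayesian neural networks sampled by
    Markov chain Monte Carlo, combined by the chain rule
    P(change) = P(alternative) x P(change | alternative). Includes in-silico
    feature-removal analysis (normalized feature effects), enrichment
    percentiles against reference exon sets, BED export of motif tracks,
    query matching against a triplet database by seed-and-extend alignment,
    expression-filter construction of non-tissue-dependent negative sets with
    distribution-matched subsampling, cross-validated ROC evaluation, and a
    fully synthetic benchmark generator with planted regulatory motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'constructors.R'
    'formats-io.R'
    'features.R'
    'bnn.R'
    'scoring.R'
    'analysis.R'
    'query-match.R'
    'evaluation.R'
    'synthetic.R'
    'pipeline.R'
    'splicecode-package.R'
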