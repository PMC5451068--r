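Package: lncprior
Title: Integrative Prioritization of Candidate Disease-Associated Long
    Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, fully testable pipeline for identifying and ranking
    candidate disease-associated long non-coding RNAs (lncRNAs) from bulk
    transcriptomics. Combines negative-binomial differential expression in
    case/control cortex, tissue-selectivity scoring across a multi-tissue
    expression panel, a signed weighted gene co-expression network built on
    biweight midcorrelation and topological overlap with module detection,
    permutation-based module and gene-set statistics, Fisher-exact gene-set
    enrichment with FDR control, copy-number-variant overlap counting, and a
    final module-then-CNV candidate ranking. Ships a seeded synthetic-data
    generator that plants differential expression, co-expression modules,
    brain-selective genes, risk-gene convergence and CNV hits, so every stage
    of the pipeline can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
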