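Package: fcgnet
Title: Sex-by-Stress Transcriptomic Coherence and Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential-expression, transcriptional-coherence and
    co-expression-network analysis for factorial sex-by-stress brain
    RNA-seq designs built on the Four Core Genotypes mouse model.
    Implements low-expression filtering and log2-CPM transformation,
    per-contrast differential expression with gonadal/genetic sex
    attribution, threshold-free rank-rank hypergeometric overlap (RRHO)
    coherence maps between brain regions, weighted co-expression network
    construction with topological overlap and module detection, module
    preservation Z scores, module differential connectivity (MDC)
    permutation tests under two shuffling schemes, and condition-specific
    hub-gene identification via an N-hop neighborhood statistic.  A
    negative-binomial simulator with planted sex, stress and module
    structure makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
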