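Package: divMotif
Title: Divisive Hierarchical Clustering of ChIP-Seq Peak Sequences for
    Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Partitions ChIP-seq peak sequences into clusters of similar
    fixed-width windows by top-down (divisive) hierarchical clustering,
    exploring window shifts and both strands. Cluster membership is scored
    with a Dirichlet-multinomial marginal likelihood over position-wise
    nucleotide counts; candidate splits must pass a log-likelihood-ratio
    significance threshold and a replicate reproducibility test based on
    the adjusted Rand index, so motifs and extended sequence features are
    discovered without prior knowledge of motif number or length. Includes
    a synthetic benchmark generator that plants Dirichlet-sampled
    core/flank motifs in uniform background sequences, and evaluation of
    predicted clusterings against known labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
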