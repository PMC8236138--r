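Package: chipzone
Title: Direct TF-DNA Binding Site Calling from ChIP-Seq Peaks
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Calls high-confidence, direct transcription factor binding
    sites (TFBSs) inside ChIP-seq peaks by combining computational and
    experimental evidence. For each dataset the package optimizes a JASPAR
    position weight matrix against GC-matched background sequences with a
    ranking-perceptron strategy, detects a dataset-specific enrichment zone
    on the (distance-to-summit, PWM-score) plane by maximum-entropy
    thresholding, and keeps at most one best-scoring site per peak inside
    the zone. Quality-control filters (motif similarity to the canonical
    profile and summit centrality) split results into permissive and robust
    collections. Downstream utilities cluster sites into cis-regulatory
    modules, build motif archetypes and archetypal loci, run Fisher-exact
    region-set enrichment in three universe modes, and compute region
    statistics (genome coverage, chromosome-preserving shuffles, relative
    distances, enhancer expression specificity, pairwise co-localization).
    Seeded synthetic-fixture generators provide genomes, motifs and
    motif-planted peak sets with truth tables for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
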