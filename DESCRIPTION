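Package: rankrecover
Title: Ranking-and-Recovery Inference of Transcription Factor Regulons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transcription factor (TF) motifs and ChIP tracks enriched
    in a co-expressed gene set using a genome-wide ranking-and-recovery
    approach. Regulatory search spaces around transcription start sites are
    scored for homotypic clusters of motif sites with a log-likelihood-ratio
    cluster model, per-species rankings are aggregated by rank order
    statistics into one whole-universe gene ranking per motif or track, and
    enrichment of an input gene set is measured by the area under the
    cumulative recovery curve (AUC) in the top of each ranking, normalized to
    an enrichment score (NES) within each feature collection. Leading-edge
    analysis selects the optimal subset of direct-target genes, enriched
    motifs are mapped to candidate TFs through a motif-TF association graph
    (direct annotation, TF homology, motif similarity), and per-TF regulons
    are assembled and optionally aggregated over many gene sets into
    meta-regulons. A synthetic-data generator produces complete multi-species
    inputs with planted homotypic site clusters so the whole pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
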