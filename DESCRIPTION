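Package: phosphoTMT
Title: Multiplexed TMT Phosphoproteomics: Normalization, Differential
    Phosphorylation, Temporal Clustering and Motif Enrichment
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multiplexed isobaric-label
    (TMT) phosphoproteomics experiments with pooled bridge channels. Implements
    two-step reporter-ion normalization (bridge then channel-median), PSM to
    phosphopeptide aggregation and phosphopeptide-to-protein correction,
    localization-score filtering and mapping of phosphosites onto protein
    coordinates with flanking-window extraction, per-phosphopeptide
    differential statistics with pi-score prioritization, k-means temporal
    clustering with elbow-based model selection, iterative binomial (motif-x
    style) consensus-motif discovery, consensus-library kinase assignment with
    per-cluster enrichment, and hypergeometric over-representation analysis of
    annotation sets. Includes a synthetic multi-plex data generator with
    planted temporal archetypes, embedded kinase motifs and full ground truth
    for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Normalization, Clustering,
    DifferentialExpression
RoxygenNote: 7.3.3
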