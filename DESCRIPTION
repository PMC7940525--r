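Package: transeg
Title: Multi-Tier Analysis of Transgressive Salinity Tolerance in Rice
    Recombinant Inbred Lines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies transgressive salinity-tolerance segregants in
    recombinant inbred line (RIL) populations by a multi-tier analysis:
    formula-defined physio-biochemical assay indices (electrolyte leakage,
    lipid peroxidation, Na+/K+ content, standard-curve quantification),
    min-max normalized 1-10 scoring aggregated into an Aggregate Phenotypic
    Score (APS), trait-matrix hierarchical clustering with bootstrap support,
    growth-curve stress-penalty ("fork") detection with fork-angle and
    projected-shoot-area ratios, hyperspectral per-band variance profiling,
    k-means++ and PCA structure analysis of metabolite matrices, and
    per-genotype mutual-rank co-expression networks around bait genes with
    cross-genotype rewiring statistics. A seeded synthetic-data generator
    encodes the coupling-uncoupling model of transgressive segregation (one
    large-effect core locus plus many small-effect peripheral loci with
    epistatic synergies and drags) so that the whole pipeline is testable
    without external data.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Transcriptomics, Network, Clustering, Phenotype
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'aps.R'
    'assays.R'
    'growth.R'
    'io.R'
    'networks.R'
    'pipeline.R'
    'structure.R'
    'synthetic.R'
    'utils.R'
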