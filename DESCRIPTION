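Package: strainvar
Title: Intra- and Inter-Strain Variability Analysis for Multi-Strain
    Rat Liver Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for dissecting mRNA-abundance variability across
    panels of rat strains and crossbred lines: per-gene partitioning of
    variance into within-strain (W) and between-strain (B) components
    with the W/T ratio, empirical-Bayes moderated linear models encoding
    strain ancestry and AHR genotype, heritability analysis of cross
    lines (directional genetics versus interacting loci), divisive
    hierarchical clustering (DIANA), Gene-Ontology-style enrichment with
    permutation false-discovery control, position-weight-matrix motif
    enrichment with a five-null permutation scheme, genome hotspot
    scanning, and cross-platform/cross-species concordance. Includes a
    synthetic-data generator emulating a five-population, four-replicate
    microarray design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    mclust,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    cluster,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
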