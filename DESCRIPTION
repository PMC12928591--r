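Package: cladecomp
Title: Comparative Gene-Annotation Reconciliation and Molecular Evolution Across a Clade
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clade-scale comparative gene annotation and downstream
    molecular-evolution analyses. Reconciles a comparative (lift-over) and a de
    novo annotation of the same genome into a single gene set, computes
    CDS-level concordance metrics (precision, recall, Jaccard), partitions a
    divergence-scaled species tree into reference-anchored subclades for
    lift-over annotation, filters and classifies hierarchical orthologous
    groups (HOGs) by conservation depth and breadth, applies occupancy-based
    alignment end-trimming and masked-sequence removal, estimates the strength
    of selection on synonymous codon usage (S) from expression-binned coding
    sequences with bootstrap confidence intervals, and fits maximum-likelihood
    phylogenetic mixed models (phylogenetic heritability, fixed effects,
    bivariate phylogenetic correlations, ancestral node prediction). A full
    synthetic-data layer generates every input with known ground truth so the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    phangorn,
    optparse
Config/testthat/edition: 3
biocViews: Annotation, Phylogenetics, ComparativeGenomics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alignment-post.R'
    'annotation-merge.R'
    'annotation-qc.R'
    'clade-partition.R'
    'cladecomp-package.R'
    'codon-usage.R'
    'core-io.R'
    'orthology-classify.R'
    'phylo-mixed.R'
    'synthetic-data.R'
    'utils.R'
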