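---
title: "cladecomp: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cladecomp: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cladecomp` implements the computational core of a clade-scale
comparative annotation workflow: reconciling paired annotations of each
genome, measuring their concordance, partitioning the species tree into
lift-over subclades, classifying hierarchical orthologous groups
(HOGs), filtering codon alignments, estimating selection on synonymous
codon usage, and fitting phylogenetic mixed models to species traits.
This vignette explains the models and the decisions behind each stage,
including where the published conventions the package follows leave
genuine freedom and what was chosen in those gaps.

## Data containers and coordinate conventions

Gene models live in an `AnnotationSet`: a named `GRangesList` of CDS
intervals per gene with a per-gene source tag. Coordinates are 1-based
inclusive (GFF3 native) everywhere a user sees them; interval
arithmetic happens inside GenomicRanges, so no manual off-by-one
conversions occur anywhere in the package. Multi-isoform genes are
collapsed at read time to the isoform with the longest summed CDS —
downstream comparisons are per gene, not per transcript, and the
longest isoform is the conventional representative when the upstream
annotation does not mark a canonical one. Ties are broken by transcript
id so reading is deterministic. The GFF3 phase column is written
correctly but ignored on reading: CDS lengths are computed from
intervals only.

Alignments (`MsaBlock`) preserve case because upstream cleaning tools
mark suspect residues by lowercasing them; the MACSE frameshift
character `!` is converted to `N` so the alphabet stays closed while
column structure is preserved.

## Annotation reconciliation

Two annotations of the same genome are compared through a bipartite
graph whose edges are CDS-footprint overlaps of at least 1 bp on the
same sequence and strand. Requiring the same strand treats antisense
nested genes as distinct loci, which they are. The 1 bp edge threshold
deliberately differs from the >90% threshold used for quality metrics:
merging needs to see *any* competing model for a locus, while QC asks
whether two models agree *well*.

Connected components resolve as follows: one-to-one components keep the
gene with the longer CDS (ties keep the comparative side, consistent
with its preference elsewhere); one-to-many and many-to-one components
keep the comparative genes and drop the de novo ones, because the
comparative models carry cross-species support and fragmented de novo
models would otherwise inflate gene counts; many-to-many components —
rare and unaddressed by the convention the rules come from — resolve
the same way, extending the comparative preference. Non-overlapping
genes are kept only when their CDS exceeds 150 nt, applied to both
sources symmetrically (the convention is source-ambiguous; symmetric
application is the conservative reading, and `applyMinLenTo` exposes
the alternatives).

One property the rules do *not* have: with boundary-jitter noise only,
the merged set's base-level Jaccard against the truth is not guaranteed
to reach the better input's value. Picking the longer model of a 1:1
pair favours boundary extensions, which grows the union term. What the
rules do guarantee — one model per locus, the longer of the pair — is
what the tests assert.

## Concordance metrics

Precision is the fraction of query genes for which some *single*
reference gene covers strictly more than 90% of the query CDS; recall
reverses the roles and the denominator. Matching to the single best
partner rather than the union of partners penalizes fragmentation: two
half-models each below threshold leave the reference gene unmatched.
The strict inequality follows the ">90%" convention exactly. Jaccard
similarity is base-level and strand-aware by default (a genome position
counts once per strand); a gene-level variant is available behind the
`level` flag since the granularity is a genuine free choice.

## Subclade partitioning

The species tree used here is divergence-scaled (expected
substitutions/site). A preorder traversal accepts a clade as a
lift-over subclade when it contains a reference species, spans 3–15
species, and its diameter (maximum leaf-to-leaf patristic distance)
stays within a threshold searched on a 12-step geometric ladder from
0.005 to 0.35. The ladder visits tight thresholds first so densely
sampled regions form tight subclades before looser ones are allowed;
only the endpoints are conventional, the 12-step geometric spacing is
this package's choice. "Phylogenetic distance" is reference-point
ambiguous in the convention; clade diameter is the default and
max-distance-from-reference is available via `measure`.

Species farther than 0.35 from every reference go to the global
fallback (annotated directly from the distant model species in the
original workflow). Two remediation passes handle the leftovers:
unplaced species are absorbed into a compatible accepted subclade
(capacity and diameter permitting), and isolated reference
neighbourhoods that cannot reach three species within 0.35 still form
subclades, flagged `undersized`, rather than being discarded — a
two-species reference clade is still the right lift-over unit for its
members.

## HOG filtering and classification

HOGs are retained with at least two species and more than three
sequences (both bounds exactly as conventionally stated — a
three-sequence HOG is dropped). Classification labels follow Table-1
style definitions: *universal* means at least `ceiling(0.99 × N)`
species of the N-species universe — ceiling, because flooring would
admit sets below 99% (297/301 = 98.7%); *ancient* means the species
MRCA is at least 50 My old and at least 30 species are represented.
The MRCA age is computed from the species present in the HOG, not from
a reconciled origin node, because that is what a membership table plus
a time tree can support. Classification is validated against truth
labels computed by brute force (an exhaustive node scan over the
simulation record) on simulated gain/loss matrices.

## Alignment post-filters

End trimming removes columns from each end while occupancy (non-gap
fraction) is below 70%, stopping at the first column at or above the
threshold — "at least 70%" is inclusive. With `codonAware = TRUE`
(default) each trim is rounded *outward* to whole codons: rounding
inward would restore columns the rule had rejected. Masked-sequence
removal drops rows with more than 80% (strictly) of residues masked;
gaps are excluded from the denominator because the rule concerns
residues.

## Codon usage and the S statistic

S is estimated only at the nine amino acids whose entire codon set is
two-fold degenerate (Phe, Tyr, His, Gln, Asn, Lys, Asp, Glu, Cys). The
two-fold halves of the six-fold Leu, Ser and Arg families are excluded
because their synonym sets extend beyond a single third-position
contrast. Genes are ranked by expression and split into 20 near-equal
bins; the optimal codon of each family is the more frequent codon in
the top bin (ties go to the GC-ending codon, the usual optimal codon in
the taxa that motivated the method). The reference set is all genes
outside the top bin — the convention does not define "reference", and
all-but-top maximizes the reference sample while keeping the sets
disjoint (`refSet = "all_genes"` gives the alternative). A 0.5
pseudocount (Haldane–Anscombe) keeps log-odds finite at zero cells.
Per-family estimates are combined by a count-weighted mean (pooled
counts available via `aggregation`), and bootstrap replicates resample
genes with replacement within every bin, re-identifying optimal codons
inside each replicate so identification uncertainty propagates into
the interval.

The N/C ratio weights each amino acid's nitrogen-to-carbon atom ratio
(free amino acid molecular formulas: Gly 1N/2C, Arg 4N/6C, Lys 2N/6C,
Trp 2N/11C, ...) by its usage frequency. GC3 is computed over third
positions of non-stop codons with no degeneracy filter (Met and Trp
included), the conventional definition. The amino-acid PCA is a
column-centred covariance eigendecomposition with a deterministic sign
convention (each component's largest-magnitude loading is positive).

## Phylogenetic mixed model

The phylogenetic correlation matrix of an ultrametric tree is
`A[i,j] = depth(MRCA(i,j)) / depth(tree)`, the Brownian-motion
correlation structure. The univariate model
`y ~ N(X beta, V (h2 A + (1 − h2) I))` is estimated by maximum
likelihood: after rotating into A's eigenbasis the likelihood at fixed
h2 has closed-form GLS `beta` and variance, and the scalar profile over
h2 ∈ [0, 1] is maximized by bounded search (tolerance 1e-8) with the
boundary values checked explicitly. ML point estimation with
profile/Wald intervals deliberately replaces the Bayesian MCMC used in
comparable analyses: it is deterministic and testable and targets the
same estimands (heritability, fixed-effect contrasts), though posterior
summaries are not reproduced. When the profile likelihood is flat —
a star phylogeny makes `A = I`, confounding the two variance
components — the fit is flagged non-identifiable. Ancestral node values
are predicted as the GLS intercept plus the BLUP of the phylogenetic
random effect under the fitted covariance; at the root the BLUP is zero
and the prediction equals the intercept, which the tests assert.

The bivariate model has covariance `P ⊗ A + R ⊗ I`, parameterized by
log standard deviations and Fisher-transformed correlations; after the
same eigenrotation the likelihood factorizes into per-species 2×2
problems, with `beta` profiled out by GLS inside each evaluation. The
phylogenetic correlation gets a profile-likelihood 95% interval by
bisection on the likelihood-ratio cutoff. A full multi-trait model is
deliberately reduced to univariate plus pairwise bivariate fits: every
reported quantity (heritabilities, pairwise phylogenetic correlations)
is expressible that way.

## What the synthetic data emulate — and what they do not

The generators reproduce the *structure* of the real inputs under
drosophilid-scale defaults: a pure-birth (Yule) time tree rescaled to a
47-My crown — only the induced covariance matters downstream, so the
birth-death posterior tree of a real analysis is not needed; genomes
of ~14,549 genes with mean CDS length 1.6 kbp; annotation corruption by
gene drops, splits into abutting models, fusions of neighbours, ±30 bp
boundary jitter and spurious 90–300 bp genes, all at 5% default rates
(plausible magnitudes for automated annotation error; the exact rates
are free parameters of `simConfig`); HOG presence/absence evolved by
Poisson gains on branches and exponential loss per lineage; coding
sequences with i.i.d. sites whose two-fold families follow a logistic
expression-class model (the estimator's own generative assumption) and
a proteome-like amino-acid composition; traits drawn exactly from the
phylogenetic mixed model. Selection is simulated only at the nine
two-fold families because the estimator reads nothing else; four-fold
and six-fold sites are drawn uniformly within synonym sets.

None of this emulates intron length distributions, within-genome
composition heterogeneity, expression-rank misassignment between
species, alignment error, or assembly artefacts. Passing tests
therefore demonstrate that each stage implements its rules exactly and
that the estimators recover known truth *under their own model
assumptions* — not that those assumptions hold in any particular real
genome set.

## Problem sizes and numerical choices

The test suite exercises the estimators at the scale the estimands
need: S recovery uses 12,000 genes of 510 codons (~1.5 kbp, the
drosophilid mean) in 20 bins with 1,000 bootstrap replicates over 100
simulations; mixed-model recovery uses 300-leaf trees with 50–100
replicates per condition; rule-level oracles use 500 corrupted
annotation pairs of ~50 genes and 200 random partitions of 20–300-leaf
trees (depths 1–2 substitutions/site, so the 0.35 threshold bites).
Partition validity, trimming boundaries and merge decisions are checked
against independent brute-force implementations.

Numerical details worth knowing: ultrametricity is checked at relative
tolerance 1e-6; eigenvalues of A are floored at 0 when simulating and
at 1e-12 when inverting; bootstrap CIs are percentile (type-7
quantiles); the bivariate optimizer bounds Fisher-z parameters at ±6
(correlations within ±0.99999) and restarts from jittered states on
failure; all generators route randomness through a seed argument and
restore the caller's RNG state, so identical seeds give byte-identical
outputs regardless of context.

## Known limitations

- The merge rules operate on CDS intervals only; UTRs and isoform
  structure are out of scope.
- `fitPmm` assumes Gaussian traits and a Brownian correlation
  structure; non-Gaussian responses and measurement-error models are
  not supported.
- The S estimator assumes shared mutational patterns between the high
  and reference sets and conserved expression ranks across species;
  violations bias S, not just widen its interval.
- Subclade partitioning guarantees monophyly for ladder-accepted
  clades but an absorbed leftover species may make a subclade
  non-monophyletic; such species are exactly those the strict rules
  could not place.
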