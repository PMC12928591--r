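# cladecomp

Comparative gene-annotation reconciliation and molecular-evolution
analyses across a clade of species, with a synthetic-data layer that
makes every stage testable against known ground truth.

Clade-scale annotation projects typically annotate each genome twice —
once by lift-over from a curated reference through a whole-genome
alignment (e.g. CAT) and once de novo from RNA-seq and protein evidence
(e.g. BRAKER3) — and then reconcile the two gene sets, place genes into
hierarchical orthologous groups (HOGs), align and filter coding
sequences, and ask evolutionary questions of the resulting traits.
`cladecomp` implements the bespoke computational stages of such a
pipeline for users who have the standard upstream tools' outputs (GFF3,
FASTA, Newick, OrthoFinder `N0.tsv`) in hand:

- **Annotation reconciliation** (`classifyOverlaps`,
  `mergeAnnotations`): build the bipartite CDS-overlap graph between
  the two gene sets; one-to-one components keep the longer CDS,
  one-to-many/many-to-one components keep the comparative (cat) side,
  and non-overlapping genes are retained only when their CDS exceeds
  150 nt.
- **Concordance metrics** (`precisionRecall`, `jaccardCds`): precision
  and recall at >90% CDS overlap against a reference annotation and
  the base-level Jaccard similarity of CDS footprints.
- **Reference-clade partitioning** (`partitionSubclades`,
  `chooseReference`): preorder decomposition of a divergence-scaled
  species tree into subclades of 3–15 species anchored on a reference,
  with a distance-threshold ladder from 0.005 to 0.35
  substitutions/site and a global fallback for species farther than
  0.35 from every reference.
- **HOG filtering and classification** (`filterHogs`, `classifyHogs`):
  keep HOGs with ≥2 species and >3 sequences; label HOGs universal
  (≥99% of species, by ceiling), ancient (species MRCA ≥50 My and ≥30
  species), single-copy, and reference-containing.
- **Alignment post-filters** (`trimEnds`, `dropMaskedSequences`): trim
  alignment ends until a column reaches 70% occupancy (inclusive,
  optionally codon-aware) and drop sequences with more than 80%
  (strictly) of residues masked.
- **Codon usage and composition** (`compositionProfile`,
  `estimateSFromCds`, `bootstrapS`, `aaPca`): GC, GC3, non-coding GC,
  amino-acid frequencies, the usage-weighted N/C atom ratio, and the
  strength of selection on synonymous codon usage.
- **Phylogenetic mixed models** (`phyloCov`, `fitPmm`,
  `fitBivariatePmm`): maximum-likelihood estimation of phylogenetic
  heritability, fixed effects, ancestral node predictions, and
  bivariate phylogenetic correlations.
- **Synthetic data** (`simTree`, `simHogMatrix`, `simAnnotationPair`,
  `simCdsWithSelection`, `simTraits`): generators for every input
  above with known ground truth.

## The S statistic

The strength of selection on synonymous codon usage is estimated from
the nine amino acids whose codon sets are entirely two-fold degenerate
(Phe, Tyr, His, Gln, Asn, Lys, Asp, Glu, Cys). With genes ranked by
expression and split into 20 bins, the optimal codon of each family is
the more frequent codon in the top bin, and

    S_family = ln(n_opt_high / n_nonopt_high) − ln(n_opt_ref / n_nonopt_ref)

with a 0.5 pseudocount in every cell; the overall S is the count-
weighted mean over families, and confidence intervals come from
resampling genes with replacement within every expression bin. Under a
mutation–selection–drift interpretation S is the population-scaled
selection differential favouring the optimal codon in highly expressed
genes.

## The phylogenetic mixed model

For a species trait `y`, covariates `X` and the tree-derived
correlation matrix `A` (`A[i,j]` = shared root-to-MRCA path length /
tree depth),

    y ~ Normal(X beta, V * (h2 * A + (1 - h2) * I))

is fitted by profiling the likelihood over the heritability `h2` on
[0, 1], with GLS for `beta` and a closed-form variance at each `h2`.
`h2` is the phylogenetic heritability — the fraction of among-species
variance attributable to phylogeny. The bivariate model uses the
covariance `P ⊗ A + R ⊗ I` and reports the phylogenetic correlation
`rho = P12 / sqrt(P11 P22)` with a profile-likelihood interval.

## Worked example

```r
library(cladecomp)

## simulate a genome's true annotation and two noisy copies of it
truth <- simAnnotation(300, cdsLenMean = 1600, seed = 1)
pair  <- simAnnotationPair(truth, simConfig(), seed = 2)
merged <- mergeAnnotations(pair$cat, pair$braker)

annotationSummary(merged)
#>    gene_count  mean_cds_len total_cds_len
#>       327.000      1437.856    470179.000
precisionRecall(merged, truth)
#> precision    recall
#> 0.9204893 0.9633333
jaccardCds(merged, truth)
#> [1] 0.9740503

## selection on codon usage: recover a known S
sim  <- simCdsWithSelection(12000, 20, sTrue = 0.5, pRefOpt = 0.5, seed = 1)
bins <- binByExpression(sim$expression$gene_id,
                        setNames(sim$expression$rank,
                                 sim$expression$gene_id), 20)
bootstrapS(sim$cds, bins, nBoot = 1000, seed = 2)
#> Selection on codon usage: S = 0.497 (95% bootstrap CI [0.485, 0.509],
#>   1000 replicates)
#>   9 two-fold families used

## phylogenetic heritability of a simulated trait
tr <- simTree(300, crownAge = 47, seed = 3)
y  <- simTraits(tr, heritabilityTrue = 0.4, seed = 4)
fitPmm(setNames(y$trait, y$species), NULL, phyloCov(tr), tree = tr)
#> Phylogenetic mixed model fit (ML): h2 = 0.378, logLik = -382.44
#>   sigma2_phylo = 0.3503, sigma2_resid = 0.5754
#>         term  estimate        se      lower     upper
#>  (Intercept) 0.1070401 0.2280727 -0.3399741 0.5540543
```

The merged set recovers ~96% of the truth loci at >90% CDS overlap (the
corruption model drops ~5% of genes per copy and fragments/fuses
others); the S and heritability estimates land on the generating values
within sampling error.

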