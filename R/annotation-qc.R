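#' @include AllClasses.R
NULL

#' Fraction of a gene's CDS shared with another gene
#'
#' Shared CDS base pairs between two gene models divided by the CDS
#' length of the gene chosen as denominator. Genes on different
#' sequences or strands share nothing (returns 0).
#'
#' @param geneA,geneB `GRanges` of CDS intervals (one gene each), e.g.
#'   elements of [cdsIntervals()].
#' @param denominator `"a"` or `"b"`: whose CDS length divides the
#'   shared base count.
#' @return a fraction in [0, 1].
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+")
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(111, 200), "+")
#' overlapFraction(a, b, "a")  # 0.90
#' overlapFraction(a, b, "b")  # 1.00
#' @export
overlapFraction <- function(geneA, geneB, denominator = c("a", "b")) {
  denominator <- match.arg(denominator)
  geneA <- GenomicRanges::reduce(geneA)
  geneB <- GenomicRanges::reduce(geneB)
  lenA <- sum(width(geneA)); lenB <- sum(width(geneB))
  if (lenA == 0L || lenB == 0L) stop("zero-length CDS")
  shared <- sum(width(GenomicRanges::intersect(geneA, geneB,
                                               ignore.strand = FALSE)))
  shared / if (denominator == "a") lenA else lenB
}

## shared CDS bp for every overlapping (query gene, reference gene) pair
.pairSharedBp <- function(query, reference) {
  fq <- .footprints(query)
  fr <- .footprints(reference)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(fq, fr, ignore.strand = FALSE))
  if (length(hits) == 0L)
    return(data.frame(q = character(), r = character(), shared = integer()))
  ov <- width(GenomicRanges::pintersect(
    fq[S4Vectors::queryHits(hits)], fr[S4Vectors::subjectHits(hits)]))
  key <- data.frame(q = S4Vectors::mcols(fq)$gene[S4Vectors::queryHits(hits)],
                    r = S4Vectors::mcols(fr)$gene[S4Vectors::subjectHits(hits)],
                    shared = ov, stringsAsFactors = FALSE)
  stats::aggregate(shared ~ q + r, key, sum)
}

#' Overlap-based precision and recall between two annotations
#'
#' A query gene counts as a true positive when some single reference
#' gene covers strictly more than `threshold` of the query's CDS;
#' recall is the same criterion with the roles (and the denominator)
#' reversed. Matching is to the single best partner, not the union of
#' partners, so a gene fragmented into sub-threshold pieces stays
#' unmatched.
#'
#' @param query,reference non-empty [AnnotationSet-class] objects.
#' @param threshold CDS overlap fraction that must be exceeded
#'   (strictly) for a match; default 0.90.
#' @return named numeric `c(precision = , recall = )`.
#' @export
precisionRecall <- function(query, reference, threshold = 0.90) {
  if (length(query) == 0L || length(reference) == 0L)
    stop("precision/recall undefined for an empty annotation")
  pairs <- .pairSharedBp(query, reference)
  lq <- cdsLengths(query)
  lr <- cdsLengths(reference)
  qFrac <- pairs$shared / lq[pairs$q]
  rFrac <- pairs$shared / lr[pairs$r]
  matchedQ <- unique(pairs$q[qFrac > threshold])
  matchedR <- unique(pairs$r[rFrac > threshold])
  c(precision = length(matchedQ) / length(query),
    recall = length(matchedR) / length(reference))
}

#' Genome-wide Jaccard similarity of two CDS footprints
#'
#' Base-level by default: the size of the intersection over the size of
#' the union of the two strand-aware CDS base-position sets (a position
#' counts once per strand). `level = "gene"` instead counts genes
#' matched reciprocally above `threshold` against the union of genes.
#'
#' @param query,reference [AnnotationSet-class] objects on a shared
#'   `seq_id` namespace.
#' @param level `"base"` (default) or `"gene"`.
#' @param threshold reciprocal-overlap threshold for `level = "gene"`.
#' @return a fraction in [0, 1].
#' @export
jaccardCds <- function(query, reference, level = c("base", "gene"),
                       threshold = 0.90) {
  level <- match.arg(level)
  if (level == "gene") {
    pairs <- .pairSharedBp(query, reference)
    lq <- cdsLengths(query); lr <- cdsLengths(reference)
    recip <- pairs$shared / lq[pairs$q] > threshold &
      pairs$shared / lr[pairs$r] > threshold
    m <- sum(recip)
    return(m / (length(query) + length(reference) - m))
  }
  fq <- GenomicRanges::reduce(unlist(cdsIntervals(query),
                                     use.names = FALSE))
  fr <- GenomicRanges::reduce(unlist(cdsIntervals(reference),
                                     use.names = FALSE))
  sA <- sum(width(fq)); sB <- sum(width(fr))
  if (sA + sB == 0L) stop("both CDS footprints are empty")
  ## |A n B| = |A| + |B| - |A u B|, one strand-aware reduce
  uni <- sum(width(GenomicRanges::reduce(suppressWarnings(c(fq, fr)))))
  (sA + sB - uni) / uni
}

#' Per-annotation summary statistics
#'
#' @param annotation a non-empty [AnnotationSet-class].
#' @return named numeric: `gene_count`, `mean_cds_len`, `total_cds_len`.
#' @export
annotationSummary <- function(annotation) {
  if (length(annotation) == 0L) stop("empty annotation")
  len <- cdsLengths(annotation)
  c(gene_count = length(len), mean_cds_len = mean(len),
    total_cds_len = sum(len))
}
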