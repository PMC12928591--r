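#' @include AllClasses.R
NULL

## per-gene CDS footprint as a single GRanges with a gene index; the
## class invariant already guarantees within-gene disjointness, so no
## reduce is needed
.footprints <- function(annotation) {
  g <- cdsIntervals(annotation)
  fp <- unlist(g, use.names = FALSE)
  S4Vectors::mcols(fp)$gene <- rep(names(g), S4Vectors::elementNROWS(g))
  fp
}

#' Classify CDS overlaps between two annotations of one genome
#'
#' Builds a bipartite graph with an edge whenever a gene from each set
#' shares at least 1 bp of CDS footprint on the same sequence and
#' strand, and returns its connected components labelled `one_to_one`,
#' `one_to_many`, `many_to_one`, `many_to_many`, `cat_only` or
#' `braker_only`. Opposite-strand overlaps do not connect genes:
#' antisense overlap does not indicate the same locus.
#'
#' @param cat,braker [AnnotationSet-class] objects on a shared `seq_id`
#'   namespace (conventionally a comparative and a de novo annotation).
#' @return `data.frame` with one row per component: `component`,
#'   `category`, and list-columns `cat_genes`, `braker_genes`.
#' @export
classifyOverlaps <- function(cat, braker) {
  fpA <- .footprints(cat)
  fpB <- .footprints(braker)
  idsA <- geneIds(cat)
  idsB <- geneIds(braker)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(fpA, fpB, ignore.strand = FALSE))
  ga <- S4Vectors::mcols(fpA)$gene[S4Vectors::queryHits(hits)]
  gb <- S4Vectors::mcols(fpB)$gene[S4Vectors::subjectHits(hits)]
  edges <- unique(data.frame(a = ga, b = gb, stringsAsFactors = FALSE))

  ## paste0 drops zero-length arguments, so guard the empty case
  vA <- if (length(idsA)) paste0("A|", idsA) else character(0)
  vB <- if (length(idsB)) paste0("B|", idsB) else character(0)
  gph <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(vA, vB))
  if (nrow(edges))
    gph <- gph + igraph::edges(rbind(paste0("A|", edges$a),
                                     paste0("B|", edges$b)))
  comp <- igraph::components(gph)
  memb <- comp$membership
  res <- lapply(seq_len(comp$no), function(k) {
    v <- names(memb)[memb == k]
    ca <- sub("^A\\|", "", v[startsWith(v, "A|")])
    cb <- sub("^B\\|", "", v[startsWith(v, "B|")])
    nA <- length(ca); nB <- length(cb)
    cat_ <- if (nA == 1L && nB == 1L) "one_to_one"
      else if (nA == 1L && nB > 1L) "one_to_many"
      else if (nA > 1L && nB == 1L) "many_to_one"
      else if (nA > 1L && nB > 1L) "many_to_many"
      else if (nA == 1L) "cat_only" else "braker_only"
    list(ca = ca, cb = cb, category = cat_)
  })
  data.frame(component = seq_along(res),
             category = vapply(res, `[[`, "", "category"),
             cat_genes = I(lapply(res, `[[`, "ca")),
             braker_genes = I(lapply(res, `[[`, "cb")),
             stringsAsFactors = FALSE)
}

#' Per-gene merge decisions for a cat/braker annotation pair
#'
#' Applies the reconciliation rules to every overlap component:
#' one-to-one components keep the gene with the longer CDS (ties keep
#' the cat gene); one-to-many, many-to-one and many-to-many components
#' keep every cat gene and drop every braker gene; non-overlapping
#' genes are kept only when their CDS exceeds `minCdsLen` (strictly).
#'
#' @param cat,braker [AnnotationSet-class] objects; gene ids must be
#'   disjoint between the two.
#' @param minCdsLen minimum CDS length (bp, exclusive) for retaining
#'   non-overlapping genes.
#' @param applyMinLenTo which source(s) the length filter applies to for
#'   non-overlapping genes; the default filters both symmetrically.
#' @return `data.frame` with columns `gene_id`, `source`, `component`,
#'   `category`, `kept`, `reason`.
#' @seealso [mergeAnnotations()]
#' @export
mergeDecisions <- function(cat, braker, minCdsLen = 150,
                           applyMinLenTo = c("both", "braker", "cat")) {
  applyMinLenTo <- match.arg(applyMinLenTo)
  if (length(intersect(geneIds(cat), geneIds(braker))))
    stop("gene ids are shared between the two inputs; namespace them first")
  lenA <- cdsLengths(cat)
  lenB <- cdsLengths(braker)
  empty <- data.frame(gene_id = character(), source = character(),
                      component = integer(), category = character(),
                      kept = logical(), reason = character(),
                      stringsAsFactors = FALSE)
  if (length(cat) + length(braker) == 0L) return(empty)
  comps <- classifyOverlaps(cat, braker)
  rows <- vector("list", nrow(comps))
  for (k in seq_len(nrow(comps))) {
    ca <- comps$cat_genes[[k]]
    cb <- comps$braker_genes[[k]]
    category <- comps$category[k]
    decide <- function(ids, source, kept, reason)
      if (length(ids)) data.frame(gene_id = ids, source = source,
                                  component = k, category = category,
                                  kept = kept, reason = reason,
                                  stringsAsFactors = FALSE)
    rows[[k]] <- switch(category,
      one_to_one = {
        keepCat <- lenA[ca] >= lenB[cb]      # tie keeps the cat gene
        rbind(decide(ca, "cat", keepCat, "one_to_one_longest_cds"),
              decide(cb, "braker", !keepCat, "one_to_one_longest_cds"))
      },
      cat_only = {
        pass <- !(applyMinLenTo %in% c("both", "cat")) | lenA[ca] > minCdsLen
        decide(ca, "cat", unname(pass), "non_overlapping_length_filter")
      },
      braker_only = {
        pass <- !(applyMinLenTo %in% c("both", "braker")) |
          lenB[cb] > minCdsLen
        decide(cb, "braker", unname(pass), "non_overlapping_length_filter")
      },
      ## one_to_many / many_to_one / many_to_many: prefer the cat side
      rbind(decide(ca, "cat", TRUE, "multi_overlap_prefer_cat"),
            decide(cb, "braker", FALSE, "multi_overlap_prefer_cat")))
  }
  do.call(rbind, rows)
}

#' Merge a comparative and a de novo annotation into one gene set
#'
#' Reconciles two annotations of the same genome using the rules of
#' [mergeDecisions()]; retained genes keep their original identifiers,
#' intervals and source tags.
#'
#' @inheritParams mergeDecisions
#' @param species species tag for the merged set (defaults to the cat
#'   set's species).
#' @return an [AnnotationSet-class] of the retained genes.
#' @examples
#' catA <- AnnotationSet(data.frame(gene_id = "c1", seq_id = "chr1",
#'   start = 100, end = 999, strand = "+"), source = "cat")
#' brk <- AnnotationSet(data.frame(gene_id = "b1", seq_id = "chr1",
#'   start = 150, end = 1349, strand = "+"), source = "braker")
#' geneIds(mergeAnnotations(catA, brk))   # braker gene: longer CDS
#' @export
mergeAnnotations <- function(cat, braker, minCdsLen = 150,
                             applyMinLenTo = c("both", "braker", "cat"),
                             species = speciesName(cat)) {
  dec <- mergeDecisions(cat, braker, minCdsLen = minCdsLen,
                        applyMinLenTo = applyMinLenTo)
  keptCat <- dec$gene_id[dec$kept & dec$source == "cat"]
  keptBraker <- dec$gene_id[dec$kept & dec$source == "braker"]
  genes <- suppressWarnings(
    c(cdsIntervals(cat)[match(keptCat, geneIds(cat))],
      cdsIntervals(braker)[match(keptBraker, geneIds(braker))]))
  new("AnnotationSet", species = as.character(species), genes = genes)
}
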