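#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList granges strand seqnames start end width
#' @importFrom IRanges IRanges
NULL

## ---------------------------------------------------------------------------
## AnnotationSet: one genome's protein-coding gene models
## ---------------------------------------------------------------------------

#' AnnotationSet: a set of protein-coding gene models for one genome
#'
#' An `AnnotationSet` holds one `GRanges` of CDS intervals per gene
#' (a named `GRangesList`), together with a per-gene `source` tag
#' (e.g. `"cat"`, `"braker"`, `"refseq"`) stored in the list-level
#' metadata columns. Coordinates are 1-based inclusive genomic
#' coordinates, the GFF3 native convention. Multi-isoform genes are
#' collapsed to a single model (the longest-CDS isoform) at read time.
#'
#' @slot species single species identifier (may be `NA`).
#' @slot genes named `GRangesList`; each element is the ordered,
#'   non-overlapping CDS intervals of one gene, all on one sequence and
#'   one strand. `mcols(genes)$source` carries the per-gene source tag.
#'
#' @seealso [readGFF3()], [writeGFF3()], [extractCds()]
#' @export
setClass("AnnotationSet",
  representation(species = "character", genes = "GRangesList"))

setValidity("AnnotationSet", function(object) {
  g <- object@genes
  msgs <- character()
  ids <- names(g)
  if (length(g) > 0L) {
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
      msgs <- c(msgs, "all genes must be named by gene_id")
    else if (anyDuplicated(ids))
      msgs <- c(msgs, sprintf("duplicated gene_id: %s",
                              ids[duplicated(ids)][1L]))
    src <- S4Vectors::mcols(g)$source
    if (is.null(src) || length(src) != length(g))
      msgs <- c(msgs, "mcols(genes)$source must tag every gene")
    nIv <- S4Vectors::elementNROWS(g)
    if (any(nIv == 0L))
      msgs <- c(msgs, "every gene must have at least one CDS interval")
    unl <- unlist(g, use.names = FALSE)
    grp <- rep.int(seq_along(g), nIv)
    first <- cumsum(c(1L, nIv[-length(nIv)]))
    sq <- as.integer(GenomicRanges::seqnames(unl))
    st <- as.integer(GenomicRanges::strand(unl))
    if (any(sq != sq[first][grp]) || any(st != st[first][grp]))
      msgs <- c(msgs, "each gene must lie on a single sequence and strand")
    ## within-gene disjointness, checked flat for speed
    sv <- GenomicRanges::start(unl); ev <- GenomicRanges::end(unl)
    o <- order(grp, sv)
    gg <- grp[o]; so <- sv[o]; eo <- ev[o]
    same <- gg[-1L] == gg[-length(gg)]
    if (length(same) && any(so[-1L][same] <= eo[-length(eo)][same]))
      msgs <- c(msgs, "CDS intervals within a gene must be non-overlapping")
  }
  if (length(object@species) != 1L)
    msgs <- c(msgs, "'species' must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotationSet
#'
#' @param genes a named `GRangesList` of per-gene CDS intervals, or a
#'   `data.frame` with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand` and optionally `source` (one row per CDS interval,
#'   1-based inclusive).
#' @param species species identifier.
#' @param source default source tag used when `genes` carries none.
#' @return an [AnnotationSet-class] object.
#' @examples
#' df <- data.frame(gene_id = "g1", seq_id = "chr1",
#'                  start = c(101, 301), end = c(200, 400), strand = "+")
#' AnnotationSet(df, species = "spA", source = "cat")
#' @export
AnnotationSet <- function(genes, species = NA_character_, source = "unknown") {
  if (is.data.frame(genes)) {
    stopifnot(all(c("gene_id", "seq_id", "start", "end", "strand") %in%
                    names(genes)))
    if (nrow(genes) == 0L) {
      grl <- GenomicRanges::GRangesList()
    } else {
      lev <- unique(genes$gene_id)
      genes <- genes[order(match(genes$gene_id, lev), genes$start), ,
                     drop = FALSE]
      gr <- GenomicRanges::GRanges(genes$seq_id,
                                   IRanges::IRanges(genes$start, genes$end),
                                   strand = genes$strand)
      grl <- S4Vectors::split(gr, factor(genes$gene_id, lev))
      src <- if ("source" %in% names(genes))
        as.character(genes$source[!duplicated(genes$gene_id)])
      else rep(source, length(grl))
      S4Vectors::mcols(grl)$source <- unname(src)
    }
    genes <- grl
  }
  if (is.null(S4Vectors::mcols(genes)$source))
    S4Vectors::mcols(genes)$source <- rep(source, length(genes))
  new("AnnotationSet", species = as.character(species), genes = genes)
}

## ---------------------------------------------------------------------------
## HogMatrix: hierarchical orthologous group membership
## ---------------------------------------------------------------------------

#' HogMatrix: HOG -> species -> gene membership
#'
#' Long-format membership of genes in Hierarchical Orthologous Groups
#' (HOGs), plus the ordered universe of species the table was built
#' over. A species may be absent from a HOG; where present it carries
#' one or more gene identifiers.
#'
#' @slot membership `data.frame` with character columns `hog`,
#'   `species`, `gene`; one row per (HOG, species, gene).
#' @slot speciesUniverse ordered character vector of all species
#'   considered (column order of the source table).
#' @slot hogIds character vector of HOG identifiers in input order
#'   (HOGs may legitimately have zero rows after filtering).
#' @seealso [readHogTable()], [classifyHogs()], [filterHogs()]
#' @export
setClass("HogMatrix",
  representation(membership = "data.frame", speciesUniverse = "character",
                 hogIds = "character"))

setValidity("HogMatrix", function(object) {
  m <- object@membership
  msgs <- character()
  if (!all(c("hog", "species", "gene") %in% names(m)))
    msgs <- c(msgs, "membership needs columns hog, species, gene")
  else {
    if (!all(m$species %in% object@speciesUniverse))
      msgs <- c(msgs, "membership species outside speciesUniverse")
    if (!all(m$hog %in% object@hogIds))
      msgs <- c(msgs, "membership hog outside hogIds")
    if (any(!nzchar(m$gene)))
      msgs <- c(msgs, "empty gene identifiers in membership")
  }
  if (anyDuplicated(object@hogIds))
    msgs <- c(msgs, "duplicated HOG ids")
  if (anyDuplicated(object@speciesUniverse))
    msgs <- c(msgs, "duplicated species in universe")
  if (length(msgs)) msgs else TRUE
})

#' Construct a HogMatrix
#'
#' @param membership `data.frame` with columns `hog`, `species`, `gene`.
#' @param speciesUniverse all species considered; defaults to the
#'   species present in `membership`.
#' @param hogIds all HOG ids; defaults to those present in `membership`.
#' @return a [HogMatrix-class] object.
#' @export
HogMatrix <- function(membership,
                      speciesUniverse = sort(unique(membership$species)),
                      hogIds = unique(membership$hog)) {
  membership <- data.frame(hog = as.character(membership$hog),
                           species = as.character(membership$species),
                           gene = as.character(membership$gene),
                           stringsAsFactors = FALSE)
  new("HogMatrix", membership = membership,
      speciesUniverse = as.character(speciesUniverse),
      hogIds = as.character(hogIds))
}

## ---------------------------------------------------------------------------
## MsaBlock: a (possibly codon-aware) multiple sequence alignment
## ---------------------------------------------------------------------------

#' MsaBlock: a nucleotide multiple sequence alignment with soft masking
#'
#' Rows are equal-length aligned sequences over the alphabet
#' `A C G T a c g t N n -`; lowercase letters mark residues masked by an
#' upstream alignment-cleaning step. The MACSE frameshift character `!`
#' is converted to `N` on input so the alphabet stays closed while the
#' column structure is preserved.
#'
#' @slot seqs named character vector of aligned rows (equal `nchar`).
#' @seealso [readMsa()], [trimEnds()], [dropMaskedSequences()]
#' @export
setClass("MsaBlock", representation(seqs = "character"))

setValidity("MsaBlock", function(object) {
  s <- object@seqs
  msgs <- character()
  if (length(s)) {
    if (is.null(names(s)) || anyDuplicated(names(s)))
      msgs <- c(msgs, "rows must have unique names")
    if (length(unique(nchar(s))) > 1L)
      msgs <- c(msgs, "all rows must have equal length")
    bad <- grepl("[^ACGTNacgtn-]", s)
    if (any(bad))
      msgs <- c(msgs, sprintf("illegal characters in row '%s'",
                              names(s)[bad][1L]))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an MsaBlock
#'
#' @param seqs named character vector of aligned rows; MACSE `!`
#'   frameshift marks are converted to `N`.
#' @return an [MsaBlock-class] object.
#' @export
MsaBlock <- function(seqs) {
  seqs <- gsub("!", "N", seqs, fixed = TRUE)
  new("MsaBlock", seqs = seqs)
}

## ---------------------------------------------------------------------------
## CodonSelectionEstimate
## ---------------------------------------------------------------------------

#' CodonSelectionEstimate: strength of selection on codon usage (S)
#'
#' The S statistic: the log-odds difference in optimal-codon frequency
#' between a highly expressed gene set and a reference gene set,
#' aggregated over the nine amino acids whose codon sets are entirely
#' two-fold degenerate, with optional bootstrap confidence interval.
#'
#' @slot S overall estimate (count-weighted mean of per-family log-odds
#'   differences by default).
#' @slot perFamily `data.frame` with one row per usable two-fold family:
#'   `family`, `optimal`, `p_high`, `p_ref`, `S_family`, `weight`.
#' @slot ciLow,ciHigh percentile bootstrap 95% bounds (`NA` when no
#'   bootstrap was run).
#' @slot nBoot number of bootstrap replicates (0 without bootstrap).
#' @seealso [estimateS()], [bootstrapS()]
#' @export
setClass("CodonSelectionEstimate",
  representation(S = "numeric", perFamily = "data.frame",
                 ciLow = "numeric", ciHigh = "numeric", nBoot = "integer"))

## ---------------------------------------------------------------------------
## PMMFit / BivariatePMMFit
## ---------------------------------------------------------------------------

#' PMMFit: a fitted univariate phylogenetic mixed model
#'
#' Maximum-likelihood fit of `y ~ Normal(X beta, V (h2 A + (1 - h2) I))`
#' where `A` is the tree-derived phylogenetic correlation matrix.
#'
#' @slot beta `data.frame` of fixed effects: `term`, `estimate`, `se`,
#'   `lower`, `upper` (Wald 95%).
#' @slot sigma2p,sigma2e phylogenetic and residual variance components.
#' @slot h2 phylogenetic heritability `sigma2p / (sigma2p + sigma2e)`.
#' @slot loglik maximized log-likelihood.
#' @slot ancestral named numeric of predicted trait values at internal
#'   nodes (intercept + BLUP of the phylogenetic effect); empty when no
#'   tree was supplied.
#' @slot identifiable `FALSE` when the profile likelihood over h2 is
#'   flat within tolerance (e.g. a star phylogeny).
#' @seealso [fitPmm()]
#' @export
setClass("PMMFit",
  representation(beta = "data.frame", sigma2p = "numeric",
                 sigma2e = "numeric", h2 = "numeric", loglik = "numeric",
                 ancestral = "numeric", identifiable = "logical"))

#' BivariatePMMFit: a fitted bivariate phylogenetic mixed model
#'
#' Maximum-likelihood fit of two traits with covariance
#' `P %x% A + R %x% I`; `rhoPhylo` is the phylogenetic correlation
#' `P[1,2] / sqrt(P[1,1] P[2,2])`.
#'
#' @slot P,R 2x2 phylogenetic and residual covariance matrices.
#' @slot rhoPhylo phylogenetic correlation of the two traits.
#' @slot rhoLower,rhoUpper profile-likelihood 95% interval (`NA` when
#'   not requested).
#' @slot loglik maximized log-likelihood.
#' @slot converged optimizer convergence flag.
#' @seealso [fitBivariatePmm()]
#' @export
setClass("BivariatePMMFit",
  representation(P = "matrix", R = "matrix", rhoPhylo = "numeric",
                 rhoLower = "numeric", rhoUpper = "numeric",
                 loglik = "numeric", converged = "logical"))
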