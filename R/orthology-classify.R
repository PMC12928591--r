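#' @include AllClasses.R
NULL

#' Filter HOGs by species and sequence counts
#'
#' Retains HOGs represented in at least `minSpecies` species and
#' containing strictly more than `minGenesExclusive` sequences.
#'
#' @param matrix a [HogMatrix-class].
#' @param minSpecies minimum species count (inclusive), default 2.
#' @param minGenesExclusive gene-count threshold (exclusive), default 3
#'   (a HOG with exactly 3 sequences is dropped).
#' @return a filtered [HogMatrix-class] over the same species universe.
#' @export
filterHogs <- function(matrix, minSpecies = 2L, minGenesExclusive = 3L) {
  m <- hogMembership(matrix)
  nSp <- tapply(m$species, m$hog, function(s) length(unique(s)))
  nGenes <- table(m$hog)
  ok <- names(nSp)[nSp >= minSpecies &
                     as.vector(nGenes[names(nSp)]) > minGenesExclusive]
  HogMatrix(m[m$hog %in% ok, , drop = FALSE],
            speciesUniverse = speciesUniverse(matrix),
            hogIds = intersect(hogIds(matrix), ok))
}

#' Age of the most recent common ancestor of a species set
#'
#' Node height (time before present) of the MRCA on an ultrametric
#' tree; a single species has age 0.
#'
#' @param tree ultrametric `phylo`.
#' @param species character vector of leaf names.
#' @return age in the tree's depth units (My for a time tree).
#' @export
mrcaAge <- function(tree, species) {
  tips <- match(species, tree$tip.label)
  if (anyNA(tips))
    stop(sprintf("species '%s' not in tree",
                 species[is.na(tips)][1L]))
  nd <- ape::node.depth.edgelength(tree)
  depth <- max(nd[seq_len(ape::Ntip(tree))])
  if (length(unique(tips)) == 1L) return(0)
  depth - nd[ape::getMRCA(tree, unique(tips))]
}

#' Classify HOGs by conservation depth and breadth
#'
#' Labels each HOG: `universal` when present in at least
#' `ceiling(universalFrac * N)` of the `N` species in the universe
#' (ceiling, so 99% of 301 species means 298); `all_species` when
#' present in every one; `single_copy` when no represented species has
#' more than one gene; `ancient` when the represented species' MRCA is
#' at least `ancientAge` old and at least `ancientMinSpecies` species
#' are represented; `contains_reference_gene` when the reference
#' species is represented. `band` reports species representation as a
#' fraction-of-universe band.
#'
#' @param matrix a [HogMatrix-class].
#' @param tree ultrametric `phylo` time tree covering the matrix
#'   species.
#' @param universalFrac universal threshold as a fraction of the
#'   species universe, in (0, 1].
#' @param ancientAge minimum MRCA age (My) for `ancient`.
#' @param ancientMinSpecies minimum species count for `ancient`.
#' @param referenceSpecies optional reference species id.
#' @return `data.frame` with one row per HOG: `hog`, `n_species`,
#'   `n_genes`, `single_copy`, `universal`, `all_species`, `mrca_age`,
#'   `ancient`, `contains_reference_gene`, `band`.
#' @export
classifyHogs <- function(matrix, tree, universalFrac = 0.99,
                         ancientAge = 50, ancientMinSpecies = 30L,
                         referenceSpecies = NULL) {
  if (universalFrac <= 0 || universalFrac > 1)
    stop("'universalFrac' must be in (0, 1]")
  m <- hogMembership(matrix)
  uni <- speciesUniverse(matrix)
  if (!all(uni %in% tree$tip.label))
    stop("matrix species universe is not covered by the tree")
  N <- length(uni)
  hogs <- hogIds(matrix)
  hogs <- hogs[hogs %in% m$hog]

  nd <- ape::node.depth.edgelength(tree)
  depth <- max(nd[seq_len(ape::Ntip(tree))])
  ages <- depth - nd
  M <- ape::mrca(tree)                    # pairwise tip MRCA node ids
  tipIdx <- stats::setNames(seq_len(ape::Ntip(tree)), tree$tip.label)

  perHogSpecies <- split(m$species, factor(m$hog, hogs))
  counts <- lengths(perHogSpecies)
  nSp <- integer(length(hogs))
  age <- numeric(length(hogs))
  singleCopy <- logical(length(hogs))
  hasRef <- logical(length(hogs))
  for (i in seq_along(hogs)) {
    spAll <- perHogSpecies[[i]]
    sp <- unique(spAll)
    nSp[i] <- length(sp)
    singleCopy[i] <- length(spAll) == length(sp)
    hasRef[i] <- !is.null(referenceSpecies) && referenceSpecies %in% sp
    ## MRCA height of a set: the deepest pairwise MRCA with the first tip
    age[i] <- if (nSp[i] == 1L) 0 else {
      ti <- tipIdx[sp]
      max(ages[M[ti[1L], ti[-1L]]])
    }
  }
  out <- data.frame(
    hog = hogs, n_species = nSp, n_genes = as.integer(counts),
    single_copy = singleCopy,
    universal = nSp >= ceiling(universalFrac * N),
    all_species = nSp == N, mrca_age = age,
    ancient = age >= ancientAge & nSp >= ancientMinSpecies,
    contains_reference_gene = hasRef,
    stringsAsFactors = FALSE)
  frac <- out$n_species / N
  out$band <- cut(frac, c(0, 0.5, 0.75, 0.99, 1), right = FALSE,
                  labels = c("<50%", "50-75%", "75-99%", ">=99%"),
                  include.lowest = TRUE)
  out$band[frac >= 0.99] <- ">=99%"
  out
}

#' Per-species HOG assignment rates
#'
#' Fraction of each species' genes that appear in any HOG.
#'
#' @param matrix a [HogMatrix-class].
#' @param totals named numeric of total gene counts per species; must
#'   cover every species in the universe and be at least the per-species
#'   assigned counts.
#' @return named numeric fraction per species in the universe.
#' @export
assignmentRates <- function(matrix, totals) {
  uni <- speciesUniverse(matrix)
  if (!all(uni %in% names(totals)))
    stop(sprintf("missing total for species '%s'",
                 setdiff(uni, names(totals))[1L]))
  if (any(totals[uni] <= 0)) stop("species with a total of 0 genes")
  m <- hogMembership(matrix)
  assigned <- tapply(m$gene, m$species, function(g) length(unique(g)))
  res <- stats::setNames(numeric(length(uni)), uni)
  res[names(assigned)] <- assigned
  if (any(res > totals[uni]))
    stop("more assigned genes than the species total")
  res / totals[uni]
}
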