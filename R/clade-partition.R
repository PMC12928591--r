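#' @include AllClasses.R
NULL

## clade measure used for threshold checks
.cladeMeasure <- function(D, members, refs, measure) {
  if (length(members) < 2L) return(0)
  if (measure == "diameter") max(D[members, members])
  else {
    r <- intersect(members, refs)
    min(vapply(r, function(x) max(D[x, members]), 1))
  }
}

#' Partition a divergence-scaled species tree into reference-anchored
#' subclades
#'
#' Identifies monophyletic subclades, each containing at least one
#' reference species, whose internal divergence stays within a
#' phylogenetic distance threshold searched per region on a geometric
#' ladder from `dMin` up to `dMax`, aiming for `sizeMin`-`sizeMax`
#' species per subclade. The traversal is preorder: at each ladder step
#' the largest qualifying clade closest to the root is accepted and its
#' leaves withdrawn. Species farther than `dMax` (patristic) from every
#' reference are assigned to the global fallback. Remaining unplaced
#' species are absorbed into a compatible accepted subclade where
#' possible; isolated reference neighbourhoods that cannot reach
#' `sizeMin` within `dMax` still form (undersized) subclades rather
#' than being discarded.
#'
#' @param tree `phylo` with branch lengths in expected substitutions
#'   per site.
#' @param references character vector of reference species (subset of
#'   the leaves).
#' @param dMin,dMax distance-threshold endpoints (substitutions/site).
#' @param sizeMin,sizeMax target subclade size window.
#' @param nSteps number of geometric ladder steps between `dMin` and
#'   `dMax`.
#' @param measure `"diameter"` (maximum leaf-to-leaf patristic distance
#'   within the clade, default) or `"reference"` (maximum distance from
#'   the anchoring reference).
#' @param geneCounts,targetCount optional per-species gene counts and a
#'   target count: when a subclade holds several references, the one
#'   whose count is closest to the target anchors it (see
#'   [chooseReference()]); otherwise the lexicographically smallest
#'   reference anchors.
#' @return list with `subclades` (`data.frame`: `reference`,
#'   `n_members`, `threshold_used`, `undersized`, list-column
#'   `members`) and `fallback` (character vector of species assigned to
#'   the global fallback reference).
#' @export
partitionSubclades <- function(tree, references, dMin = 0.005, dMax = 0.35,
                               sizeMin = 3L, sizeMax = 15L, nSteps = 12L,
                               measure = c("diameter", "reference"),
                               geneCounts = NULL, targetCount = NULL) {
  measure <- match.arg(measure)
  tips <- tree$tip.label
  if (length(references) == 0L) stop("no reference species supplied")
  if (!all(references %in% tips))
    stop(sprintf("reference '%s' not in tree",
                 setdiff(references, tips)[1L]))
  references <- unique(references)
  D <- ape::cophenetic.phylo(tree)

  ## global fallback: leaves farther than dMax from every reference
  minRefDist <- apply(D[, references, drop = FALSE], 1L, min)
  fallback <- tips[minRefDist > dMax]
  remaining <- setdiff(tips, fallback)

  ## clade leaf sets in preorder (root first)
  n <- ape::Ntip(tree)
  tr <- ape::reorder.phylo(tree, "cladewise")
  cladeLeaves <- vector("list", n + tr$Nnode)
  for (v in seq_len(n)) cladeLeaves[[v]] <- tips[v]
  post <- rev(seq_len(nrow(tr$edge)))
  for (e in post) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    cladeLeaves[[par]] <- c(cladeLeaves[[par]], cladeLeaves[[child]])
  }
  preorderNodes <- unique(c(n + 1L, tr$edge[, 2L]))

  ladder <- exp(seq(log(dMin), log(dMax), length.out = nSteps))
  accepted <- list()
  for (t in ladder) {
    for (v in preorderNodes) {
      S <- intersect(cladeLeaves[[v]], remaining)
      if (length(S) < sizeMin || length(S) > sizeMax) next
      if (!any(S %in% references)) next
      if (.cladeMeasure(D, S, references, measure) > t) next
      accepted[[length(accepted) + 1L]] <-
        list(members = S, threshold = t, undersized = FALSE)
      remaining <- setdiff(remaining, S)
    }
  }

  ## absorb leftover near-reference leaves into compatible subclades
  absorb <- function(remaining) {
    for (leaf in remaining[order(minRefDist[remaining])]) {
      best <- NULL; bestT <- Inf
      for (k in seq_along(accepted)) {
        S2 <- c(accepted[[k]]$members, leaf)
        if (length(S2) > sizeMax) next
        if (!any(accepted[[k]]$members %in% references)) next
        m <- .cladeMeasure(D, S2, references, measure)
        if (m <= dMax && m < bestT) { best <- k; bestT <- m }
      }
      if (!is.null(best)) {
        accepted[[best]]$members <<- c(accepted[[best]]$members, leaf)
        accepted[[best]]$threshold <<-
          max(accepted[[best]]$threshold,
              min(c(ladder[ladder >= bestT], dMax)))
        remaining <- setdiff(remaining, leaf)
      }
    }
    remaining
  }
  remaining <- absorb(remaining)

  ## isolated reference neighbourhoods: accept even below sizeMin
  for (v in preorderNodes) {
    S <- intersect(cladeLeaves[[v]], remaining)
    if (length(S) < 1L || length(S) > sizeMax) next
    if (!any(S %in% references)) next
    m <- .cladeMeasure(D, S, references, measure)
    if (m > dMax) next
    thr <- min(c(ladder[ladder >= m], dMax))
    accepted[[length(accepted) + 1L]] <-
      list(members = S, threshold = thr, undersized = length(S) < sizeMin)
    remaining <- setdiff(remaining, S)
  }
  remaining <- absorb(remaining)

  ## anything still unplaced has no compatible reference clade
  fallback <- c(fallback, remaining)

  anchor <- vapply(accepted, function(a) {
    cand <- sort(intersect(a$members, references))
    if (length(cand) > 1L && !is.null(geneCounts) && !is.null(targetCount))
      chooseReference(cand, geneCounts, targetCount)
    else cand[1L]
  }, "")
  subclades <- data.frame(
    reference = anchor,
    n_members = vapply(accepted, function(a) length(a$members), 1L),
    threshold_used = vapply(accepted, function(a) a$threshold, 1),
    undersized = vapply(accepted, function(a) a$undersized, TRUE),
    stringsAsFactors = FALSE)
  subclades$members <- I(lapply(accepted, `[[`, "members"))
  list(subclades = subclades, fallback = fallback)
}

#' Choose a subclade's reference species by gene-count similarity
#'
#' Among candidate reference species, returns the one whose annotated
#' gene count is closest to `targetCount` (the best-annotated model
#' species' count); ties go to the lexicographically smallest name.
#'
#' @param candidates non-empty character vector of candidate species.
#' @param geneCounts named numeric of per-species gene counts.
#' @param targetCount target gene count.
#' @return a single species name.
#' @examples
#' chooseReference(c("X", "Y"), c(X = 14000, Y = 17000), 13904)  # "X"
#' @export
chooseReference <- function(candidates, geneCounts, targetCount) {
  if (length(candidates) == 0L) stop("no candidates")
  if (!all(candidates %in% names(geneCounts)))
    stop(sprintf("missing gene count for '%s'",
                 setdiff(candidates, names(geneCounts))[1L]))
  d <- abs(geneCounts[candidates] - targetCount)
  cand <- sort(candidates[d == min(d)])
  cand[1L]
}
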