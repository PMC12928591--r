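## independent brute-force oracles, written against plain base-position
## sets so they share no interval machinery with the implementation

## connected components of the bipartite CDS-overlap graph, by
## repeated frontier expansion over exact per-base intersections
bruteComponents <- function(catX, brkX) {
  nA <- length(catX); nB <- length(brkX)
  touches <- function(a, b)
    a$seq == b$seq && a$strand == b$strand &&
      length(intersect(a$pos, b$pos)) > 0
  adj <- matrix(FALSE, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    a <- catX[[i]]; b <- brkX[[j]]
    ## bounding-box prefilter only skips pairs that cannot share a base
    if (a$seq == b$seq && a$strand == b$strand &&
        min(a$pos) <= max(b$pos) && min(b$pos) <= max(a$pos))
      adj[i, j] <- touches(a, b)
  }
  seenA <- rep(FALSE, nA); seenB <- rep(FALSE, nB)
  comps <- list()
  for (i in seq_len(nA)) {
    if (seenA[i]) next
    qa <- i; qb <- integer()
    repeat {
      newB <- setdiff(which(apply(adj[qa, , drop = FALSE], 2, any)), qb)
      if (!length(newB)) break
      qb <- c(qb, newB)
      newA <- setdiff(which(apply(adj[, qb, drop = FALSE], 1, any)), qa)
      if (!length(newA)) break
      qa <- c(qa, newA)
    }
    seenA[qa] <- TRUE; seenB[qb] <- TRUE
    comps[[length(comps) + 1]] <- list(a = qa, b = qb)
  }
  for (j in which(!seenB))
    comps[[length(comps) + 1]] <- list(a = integer(), b = j)
  comps
}

## gene-by-gene keep/drop per the three reconciliation rules
bruteMergeKept <- function(cat, braker, minCdsLen = 150) {
  catX <- explodeAnnotation(cat)
  brkX <- explodeAnnotation(braker)
  comps <- bruteComponents(catX, brkX)
  kept <- character()
  for (cp in comps) {
    nA <- length(cp$a); nB <- length(cp$b)
    idsA <- vapply(catX[cp$a], `[[`, "", "id")
    idsB <- vapply(brkX[cp$b], `[[`, "", "id")
    lenA <- vapply(catX[cp$a], function(g) length(g$pos), 1)
    lenB <- vapply(brkX[cp$b], function(g) length(g$pos), 1)
    if (nA == 1 && nB == 1) {
      kept <- c(kept, if (lenA >= lenB) idsA else idsB)
    } else if (nA >= 1 && nB >= 1) {
      kept <- c(kept, idsA)
    } else if (nA == 1) {
      if (lenA > minCdsLen) kept <- c(kept, idsA)
    } else if (nB == 1) {
      if (lenB > minCdsLen) kept <- c(kept, idsB)
    }
  }
  sort(kept)
}

## per-base bit-set QC oracle
bruteQc <- function(query, reference, threshold = 0.90) {
  qx <- explodeAnnotation(query)
  rx <- explodeAnnotation(reference)
  sharedBp <- function(a, b)
    if (a$seq == b$seq && a$strand == b$strand)
      length(intersect(a$pos, b$pos)) else 0
  precOk <- vapply(qx, function(q)
    any(vapply(rx, function(r) sharedBp(q, r), 1) / length(q$pos) >
          threshold), TRUE)
  recOk <- vapply(rx, function(r)
    any(vapply(qx, function(q) sharedBp(q, r), 1) / length(r$pos) >
          threshold), TRUE)
  keys <- function(xs) unique(unlist(lapply(xs, function(g)
    paste(g$seq, g$strand, g$pos))))
  kq <- keys(qx); kr <- keys(rx)
  list(precision = mean(precOk), recall = mean(recOk),
       jaccard = length(intersect(kq, kr)) / length(union(kq, kr)))
}
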