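## shared fixture builders for the test suite

## a random multi-sequence AnnotationSet (not necessarily biologically
## laid out; used for round-trip and metric tests)
randomAnnotationSet <- function(nGenes, seed = 1, nSeqs = 3,
                                source = "cat") {
  set.seed(seed)
  rows <- lapply(seq_len(nGenes), function(i) {
    nIv <- sample(1:4, 1)
    start <- sort(sample.int(100000, nIv))
    width <- sample(10:400, nIv, replace = TRUE)
    ## force disjoint intervals
    start <- start + cumsum(c(0, head(width, -1) + 10))
    data.frame(gene_id = sprintf("%s_g%04d", source, i),
               seq_id = paste0("chr", sample.int(nSeqs, 1)),
               start = start, end = start + width - 1,
               strand = sample(c("+", "-"), 1),
               stringsAsFactors = FALSE)
  })
  AnnotationSet(do.call(rbind, rows), species = "test", source = source)
}

## plain-R view of an annotation: one list entry per gene with an
## explicit base-position vector (the representation the oracles use)
explodeAnnotation <- function(ann) {
  tab <- annotationTable(ann)
  lapply(split(tab, factor(tab$gene_id, unique(tab$gene_id))),
         function(d) list(
           id = d$gene_id[1], seq = d$seq_id[1], strand = d$strand[1],
           pos = sort(unique(unlist(Map(seq, d$start, d$end))))))
}

## random alignment with gaps and lowercase masking
randomMsa <- function(nSeq, nCol, pGap = 0.2, pMask = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), nSeq * nCol, TRUE), nSeq, nCol)
  mask <- matrix(runif(nSeq * nCol) < pMask, nSeq, nCol)
  m[mask] <- tolower(m[mask])
  gap <- matrix(runif(nSeq * nCol) < pGap, nSeq, nCol)
  m[gap] <- "-"
  MsaBlock(stats::setNames(apply(m, 1, paste, collapse = ""),
                           paste0("seq", seq_len(nSeq))))
}

## bivariate traits with known phylogenetic correlation, built directly
## from the covariance decomposition (test-side generator)
simBivTraits <- function(tree, h2 = 0.5, rho = 0.5, seed = 1) {
  A <- phyloCov(tree)
  e <- eigen(A, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
  n <- nrow(A)
  set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  u1 <- drop(L %*% z1)
  u2 <- drop(L %*% (rho * z1 + sqrt(1 - rho^2) * z2))
  y1 <- sqrt(h2) * u1 + rnorm(n, 0, sqrt(1 - h2))
  y2 <- sqrt(h2) * u2 + rnorm(n, 0, sqrt(1 - h2))
  list(y1 = stats::setNames(y1, rownames(A)),
       y2 = stats::setNames(y2, rownames(A)), A = A)
}
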