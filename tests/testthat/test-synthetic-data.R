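test_that("simTree is ultrametric at the requested depth and deterministic", {
  tr <- simTree(2, crownAge = 47, seed = 1)
  expect_equal(sort(tr$tip.label), c("s1", "s2"))
  expect_equal(unname(tr$edge.length), c(47, 47))

  tr2 <- simTree(301, crownAge = 47, seed = 5)
  d <- ape::node.depth.edgelength(tr2)[seq_len(301)]
  expect_true(max(abs(d - 47)) < 1e-9)
  expect_identical(ape::write.tree(simTree(50, seed = 9)),
                   ape::write.tree(simTree(50, seed = 9)))
  expect_false(identical(ape::write.tree(simTree(50, seed = 9)),
                         ape::write.tree(simTree(50, seed = 10))))
  expect_error(simTree(1), "at least 2")
})

test_that("HOG simulation respects loss-free and root-origin limits", {
  tr <- simTree(40, 47, seed = 2)
  ## no loss: every HOG spans all descendants of its origin
  sim <- simHogMatrix(tr, gainRate = 0.3, lossRate = 0, seed = 3)
  desc <- lapply(seq_len(40 + tr$Nnode), function(v)
    if (v <= 40) tr$tip.label[v] else
      tr$tip.label[unlist(phangorn::Descendants(tr, v, "tips"))])
  m <- hogMembership(sim$matrix)
  for (k in seq_len(nrow(sim$truth))) {
    h <- sim$truth$hog[k]
    expect_setequal(unique(m$species[m$hog == h]),
                    desc[[sim$truth$origin_node[k]]])
  }
  ## gain only at root, no loss: everything universal
  simR <- simHogMatrix(tr, gainRate = 1e-9, lossRate = 0, seed = 4,
                       rootMass = 1e10)
  expect_true(all(simR$truth$origin_node == 41))
  expect_true(all(simR$truth$universal))
  expect_true(all(simR$truth$all_species))
})

test_that("annotation corruption honours its error-rate limits", {
  truth <- simAnnotation(20, cdsLenMean = 600, seed = 11)
  clean <- simConfig(pDrop = 0, pSplit = 0, pMerge = 0, pSpurious = 0,
                     jitterBp = 0)
  pair <- simAnnotationPair(truth, clean, seed = 1)
  ## error-free copies equal truth modulo id prefix and source tag
  expect_equal(sort(sub("^cat_", "", geneIds(pair$cat))),
               sort(geneIds(truth)))
  expect_equal(unname(cdsLengths(pair$cat)[paste0("cat_", geneIds(truth))]),
               unname(cdsLengths(truth)))
  expect_true(all(pair$truthMap$error_mode == "intact"))

  ## forced split on a 1-gene truth partitions its footprint
  one <- truth[1]
  ps <- simAnnotationPair(one, simConfig(pDrop = 0, pSplit = 1, pMerge = 0,
                                         pSpurious = 0, jitterBp = 0),
                          seed = 2)
  expect_equal(length(ps$cat), 2L)
  fp <- GenomicRanges::reduce(unlist(cdsIntervals(ps$cat),
                                     use.names = FALSE))
  fpT <- GenomicRanges::reduce(unlist(cdsIntervals(one), use.names = FALSE))
  expect_equal(sum(GenomicRanges::width(fp)), sum(GenomicRanges::width(fpT)))
  expect_equal(sum(cdsLengths(ps$cat)), sum(cdsLengths(one)))

  ## forced drop empties the copy
  pd <- simAnnotationPair(truth, simConfig(pDrop = 1, pSplit = 0,
                                           pMerge = 0, pSpurious = 0,
                                           jitterBp = 0), seed = 3)
  expect_equal(length(pd$cat), 0L)
})

test_that("the annotation truth map is exhaustive", {
  truth <- simAnnotation(60, seed = 21)
  pair <- simAnnotationPair(truth, simConfig(), seed = 22)
  tm <- pair$truthMap
  derived <- c(geneIds(pair$cat), geneIds(pair$braker))
  expect_setequal(unique(tm$derived_gene_id), derived)
  spur <- tm$error_mode == "spurious"
  expect_true(all(is.na(tm$truth_gene_id[spur])))
  expect_true(all(tm$truth_gene_id[!spur] %in% geneIds(truth)))
  ## determinism
  pair2 <- simAnnotationPair(truth, simConfig(), seed = 22)
  expect_identical(geneIds(pair2$cat), geneIds(pair$cat))
  expect_identical(cdsLengths(pair2$braker), cdsLengths(pair$braker))
})

test_that("selection simulator hits its expected codon frequencies", {
  ## null case: top bin matches the reference frequency
  sim0 <- simCdsWithSelection(2000, 10, sTrue = 0, pRefOpt = 0.5,
                              seed = 31, nCodons = 210)
  fams <- twofoldFamilies()
  vocab <- as.vector(vapply(fams, identity, c(at = "", gc = "")))
  C <- cladecomp:::.geneCodonCounts(sim0$cds, vocab)
  bins <- binByExpression(sim0$expression$gene_id,
    stats::setNames(sim0$expression$rank, sim0$expression$gene_id), 10)
  gcIdx <- match(vapply(fams, `[[`, "", "gc"), vocab)
  top <- colSums(C[bins == 1, , drop = FALSE])
  pObs <- sum(top[gcIdx]) / sum(top)
  expect_lt(abs(pObs - 0.5), 0.01)

  ## logistic shift: sigma(logit(0.5) + 1) = e/(1+e)
  sim1 <- simCdsWithSelection(2000, 10, sTrue = 1, pRefOpt = 0.5,
                              seed = 32, nCodons = 210)
  expect_equal(sim1$pTop, exp(1) / (1 + exp(1)))
  C1 <- cladecomp:::.geneCodonCounts(sim1$cds, vocab)
  top1 <- colSums(C1[bins == 1, , drop = FALSE])
  expect_lt(abs(sum(top1[gcIdx]) / sum(top1) - sim1$pTop), 0.01)

  ## valid ORFs, deterministic output
  expect_true(all(Biostrings::width(sim1$cds) %% 3 == 0))
  expect_identical(as.character(sim1$cds),
                   as.character(simCdsWithSelection(2000, 10, sTrue = 1,
                     pRefOpt = 0.5, seed = 32, nCodons = 210)$cds))
  expect_error(simCdsWithSelection(5, 10), "fewer genes")
})

test_that("trait simulation matches its variance structure at the limits", {
  tr <- simTree(60, 47, seed = 41)
  ## h2 = 0: replicate covariance of unrelated tips is ~ 0, variance ~ V
  reps <- sapply(1:200, function(i)
    simTraits(tr, 0, totalVariance = 2, seed = i)$trait)
  expect_lt(abs(mean(apply(reps, 1, var)) - 2), 0.25)
  sib <- cor(reps[1, ], reps[2, ])
  expect_lt(abs(sib), 0.2)

  ## h2 = 1 with zero-length sister terminals: identical values
  toy <- ape::read.tree(text = "((A:0,B:0):2,C:2);")
  y <- simTraits(toy, 1, seed = 5)
  expect_equal(y$trait[y$species == "A"], y$trait[y$species == "B"],
               tolerance = 1e-6)
  expect_error(simTraits(tr, 0.5, fixedEffects = list(
    X = matrix(NA_real_, 60, 1, dimnames = list(tr$tip.label, "x")),
    beta = 1)), "non-finite")
})
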