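test_that("composition profile reproduces hand-counted values", {
  p <- compositionProfile(c(g1 = "ATGGCCAAA"))
  expect_equal(p$gc3, 2 / 3)
  expect_equal(sum(p$aaFreqs), 1, tolerance = 1e-9)
  ## molecular-formula checks on homopolymer coding sequences
  expect_equal(compositionProfile(c(g = strrep("GGA", 50)))$ncRatio, 0.5)
  expect_equal(compositionProfile(c(g = strrep("CGT", 50)))$ncRatio, 4 / 6)
  ## stop codons excluded from gc3 and translation
  withStop <- compositionProfile(c(g = "ATGTAA"))
  expect_equal(withStop$gc3, 1 / 1)          # only ATG's G counts
  expect_error(compositionProfile(character(0)), "empty")
  expect_warning(compositionProfile(c(a = "ATGGCC", b = "ATGG")),
                 "divisible")
})

test_that("non-coding GC is computed outside the CDS footprint", {
  ann <- AnnotationSet(data.frame(gene_id = "g1", seq_id = "chr1",
    start = 1, end = 6, strand = "+"), species = "x")
  genome <- c(chr1 = "ATGTAAGGGGCC")      # non-CDS suffix: GGGGCC
  p <- compositionProfile(c(g1 = "ATGTAA"), genome = genome,
                          annotation = ann)
  expect_equal(p$gcNoncoding, 1.0)
  expect_true(is.na(compositionProfile(c(g1 = "ATGTAA"))$gcNoncoding))
})

test_that("amino-acid frequencies are invariant to gene order and
           concatenation", {
  sim <- simCdsWithSelection(200, 5, sTrue = 0.5, pRefOpt = 0.5,
                             seed = 61, nCodons = 120)
  seqs <- as.character(sim$cds)
  a <- compositionProfile(seqs)$aaFreqs
  b <- compositionProfile(rev(seqs))$aaFreqs
  cc <- compositionProfile(paste(seqs, collapse = ""))$aaFreqs
  expect_equal(a, b)
  expect_equal(a, cc)
})

test_that("expression binning is balanced, ordered and strict", {
  r <- stats::setNames(1:7, paste0("g", 1:7))
  b <- binByExpression(names(r), r, nBins = 3)
  expect_equal(as.integer(table(b)), c(3L, 2L, 2L))
  expect_equal(unname(b[c("g1", "g2", "g3")]), c(1L, 1L, 1L))
  big <- binByExpression(sprintf("g%05d", 1:12000),
                         stats::setNames(1:12000, sprintf("g%05d", 1:12000)),
                         20)
  expect_true(all(table(big) == 600))
  expect_error(binByExpression(paste0("g", 1:2),
                               stats::setNames(1:2, paste0("g", 1:2)), 5),
               "fewer genes")
})

test_that("optimal codons come from the top bin with a GC tie-break", {
  counts <- stats::setNames(numeric(18),
    unlist(twofoldFamilies(), use.names = FALSE))
  counts["AAA"] <- 30; counts["AAG"] <- 70     # Lys -> AAG
  counts["TTT"] <- 50; counts["TTC"] <- 50     # tie -> TTC
  counts["TAT"] <- 10; counts["TAC"] <- 5      # Tyr -> TAT
  expect_warning(opt <- identifyOptimalCodons(counts), "omitted")
  expect_equal(opt[["K"]], "AAG")
  expect_equal(opt[["F"]], "TTC")
  expect_equal(opt[["Y"]], "TAT")
  expect_false("C" %in% names(opt))            # zero counts dropped
})

test_that("S follows the pseudocounted log-odds arithmetic", {
  est <- estimateS(c(AAA = 30, AAG = 70), c(AAA = 50, AAG = 50),
                   c(K = "AAG"))
  expect_equal(sValue(est), log(70.5 / 30.5) - log(50.5 / 50.5),
               tolerance = 1e-12)
  ## identical sets: S = 0
  same <- c(AAA = 40, AAG = 60)
  expect_equal(sValue(estimateS(same, same, c(K = "AAG"))), 0)
  ## antisymmetry under swapping high and reference sets
  h <- c(AAA = 31, AAG = 72, GAT = 11, GAC = 40)
  r <- c(AAA = 55, AAG = 45, GAT = 30, GAC = 22)
  opt <- c(K = "AAG", D = "GAC")
  sHR <- sValue(estimateS(h, r, opt, aggregation = "pooled"))
  sRH <- sValue(estimateS(r, h, opt, aggregation = "pooled"))
  expect_equal(sHR, -sRH, tolerance = 1e-12)
})

test_that("bootstrap CIs behave on degenerate and simulated data", {
  ## every gene identical: zero-width interval equal to S
  cds <- stats::setNames(rep("ATGAAGAAATAA", 40), paste0("g", 1:40))
  bins <- binByExpression(names(cds),
                          stats::setNames(1:40, names(cds)), 4)
  est <- suppressWarnings(bootstrapS(cds, bins, nBoot = 50, seed = 3))
  expect_equal(est@ciLow, sValue(est))
  expect_equal(est@ciHigh, sValue(est))
  ## determinism
  sim <- simCdsWithSelection(600, 6, sTrue = 0.5, pRefOpt = 0.5,
                             seed = 71, nCodons = 150)
  b <- binByExpression(sim$expression$gene_id,
    stats::setNames(sim$expression$rank, sim$expression$gene_id), 6)
  e1 <- bootstrapS(sim$cds, b, nBoot = 100, seed = 11)
  e2 <- bootstrapS(sim$cds, b, nBoot = 100, seed = 11)
  expect_identical(c(e1@ciLow, e1@ciHigh), c(e2@ciLow, e2@ciHigh))
  expect_true(e1@ciLow <= sValue(e1) && sValue(e1) <= e1@ciHigh)
  expect_error(bootstrapS(sim$cds, b, nBoot = 1), "at least 2")
})

test_that("amino-acid PCA separates constructed clusters and normalizes
           variance", {
  base <- rep(0.05, 20)
  names(base) <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  set.seed(8)
  X <- t(sapply(1:12, function(i) {
    v <- base
    d <- if (i <= 6) 0.02 else -0.02
    v["P"] <- v["P"] + d; v["I"] <- v["I"] - d
    v + stats::rnorm(20, 0, 1e-4)
  }))
  rownames(X) <- paste0("sp", 1:12)
  p <- aaPca(X)
  l1 <- p$loadings[, 1]
  top2 <- names(sort(abs(l1), decreasing = TRUE))[1:2]
  expect_setequal(top2, c("P", "I"))
  expect_lt(l1["P"] * l1["I"], 0)
  expect_equal(sum(p$varianceExplained), 1, tolerance = 1e-9)
  ## sign convention: the largest-magnitude loading is positive
  expect_gte(max(l1[top2]), abs(min(l1[top2])) - 1e-12)
  ## duplicating species leaves loadings unchanged
  p2 <- aaPca(rbind(X, X))
  expect_equal(abs(p2$loadings[, 1]), abs(p$loadings[, 1]),
               tolerance = 1e-6)
  expect_error(aaPca(matrix(0.05, 5, 20)), "zero variance")
  expect_error(aaPca(X[1:2, ]), "at least 3")
})
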