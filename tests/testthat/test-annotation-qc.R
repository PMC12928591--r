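mk <- function(df) AnnotationSet(df, species = "x")

test_that("overlapFraction follows the worked interval arithmetic", {
  a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "+")
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(111, 200), "+")
  expect_equal(overlapFraction(a, a, "a"), 1)
  expect_equal(overlapFraction(a, b, "a"), 0.90)
  expect_equal(overlapFraction(a, b, "b"), 1.00)
  dis <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 600), "+")
  expect_equal(overlapFraction(a, dis, "a"), 0)
  other <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200), "-")
  expect_equal(overlapFraction(a, other, "a"), 0)
})

test_that("precision/recall use a strict single-best-partner criterion", {
  q <- mk(data.frame(gene_id = "q1", seq_id = "chr1", start = 111,
                     end = 200, strand = "+"))
  r <- mk(data.frame(gene_id = "r1", seq_id = "chr1", start = 101,
                     end = 200, strand = "+"))
  ## covers 100% of the query but exactly 90% (not > 90%) of the reference
  pr <- precisionRecall(q, r)
  expect_equal(unname(pr["precision"]), 1.0)
  expect_equal(unname(pr["recall"]), 0.0)
  expect_equal(unname(precisionRecall(r, r)), c(1, 1))

  ## 4 shared + 1 extra disjoint query gene
  base <- data.frame(gene_id = paste0("g", 1:4), seq_id = "chr1",
                     start = c(1, 1000, 2000, 3000) + 0,
                     end = c(300, 1300, 2300, 3300), strand = "+")
  q2 <- mk(rbind(base, data.frame(gene_id = "extra", seq_id = "chr1",
                                  start = 9000, end = 9300,
                                  strand = "+")))
  r2 <- mk(base)
  pr2 <- precisionRecall(q2, r2)
  expect_equal(unname(pr2["precision"]), 0.8)
  expect_equal(unname(pr2["recall"]), 1.0)
  ## a gene split into two sub-threshold halves stays unmatched
  half <- mk(data.frame(gene_id = c("h1", "h2"), seq_id = "chr1",
                        start = c(101, 151), end = c(150, 200),
                        strand = "+"))
  expect_equal(unname(precisionRecall(half, r)["recall"]), 0)
  expect_error(precisionRecall(mk(base[0, ]), r), "empty")
})

test_that("Jaccard is base-level, strand-aware and symmetric", {
  q <- mk(data.frame(gene_id = "q1", seq_id = "chr1", start = 111,
                     end = 200, strand = "+"))
  r <- mk(data.frame(gene_id = "r1", seq_id = "chr1", start = 101,
                     end = 200, strand = "+"))
  expect_equal(jaccardCds(q, r), 0.90)
  expect_equal(jaccardCds(r, q), 0.90)
  expect_equal(jaccardCds(r, r), 1)
  dis <- mk(data.frame(gene_id = "d1", seq_id = "chr2", start = 1,
                       end = 100, strand = "+"))
  expect_equal(jaccardCds(q, dis), 0)
  ## gene-level variant
  expect_equal(jaccardCds(r, r, level = "gene"), 1)
})

test_that("precision(q,r) equals recall(r,q) and metrics match the
           per-base oracle on random genomes", {
  for (seed in 1:25) {
    q <- randomAnnotationSet(8, seed = seed, nSeqs = 2, source = "q")
    r <- randomAnnotationSet(8, seed = seed + 1000, nSeqs = 2,
                             source = "r")
    pr <- precisionRecall(q, r)
    rp <- precisionRecall(r, q)
    expect_equal(unname(pr["precision"]), unname(rp["recall"]))
    o <- bruteQc(q, r)
    expect_lt(abs(pr[["precision"]] - o$precision), 1e-12)
    expect_lt(abs(pr[["recall"]] - o$recall), 1e-12)
    expect_lt(abs(jaccardCds(q, r) - o$jaccard), 1e-12)
  }
})

test_that("adding a disjoint query gene cannot raise precision or shrink
           the footprint union", {
  r <- mk(data.frame(gene_id = paste0("r", 1:3), seq_id = "chr1",
                     start = c(1, 1000, 2000), end = c(300, 1300, 2300),
                     strand = "+"))
  q <- mk(data.frame(gene_id = paste0("q", 1:3), seq_id = "chr1",
                     start = c(1, 1000, 2000), end = c(300, 1300, 2300),
                     strand = "+"))
  qPlus <- mk(rbind(annotationTable(q),
                    data.frame(gene_id = "extra", seq_id = "chr1",
                               start = 50000, end = 50300, strand = "+",
                               source = "unknown")))
  expect_lte(precisionRecall(qPlus, r)[["precision"]],
             precisionRecall(q, r)[["precision"]])
  expect_equal(precisionRecall(qPlus, r)[["recall"]],
               precisionRecall(q, r)[["recall"]])
  expect_lt(jaccardCds(qPlus, r), jaccardCds(q, r))
})

test_that("annotation summaries report plain arithmetic", {
  a <- mk(data.frame(gene_id = c("a", "b"), seq_id = "chr1",
                     start = c(1, 1000), end = c(300, 1899),
                     strand = "+"))
  expect_equal(unname(annotationSummary(a)), c(2, 600, 1200))
  expect_error(annotationSummary(
    AnnotationSet(GenomicRanges::GRangesList(), species = "x")), "empty")
  sim <- simAnnotation(400, cdsLenMean = 1600, seed = 77)
  s <- annotationSummary(sim)
  se <- sd(cdsLengths(sim)) / sqrt(400)
  expect_lt(abs(s[["mean_cds_len"]] - 1600), 3 * se + 30)
})
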