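mkAnn <- function(df, source) AnnotationSet(df, species = "x",
                                            source = source)

test_that("overlap components are classified by connectivity and strand", {
  catA <- mkAnn(data.frame(gene_id = "c1", seq_id = "chr1", start = 100,
                           end = 200, strand = "+"), "cat")
  brk <- mkAnn(data.frame(gene_id = "b1", seq_id = "chr1", start = 150,
                          end = 250, strand = "+"), "braker")
  cc <- classifyOverlaps(catA, brk)
  expect_equal(cc$category, "one_to_one")

  brk2 <- mkAnn(data.frame(gene_id = c("b1", "b2"), seq_id = "chr1",
                           start = c(100, 310), end = c(290, 500),
                           strand = "+"), "braker")
  cat2 <- mkAnn(data.frame(gene_id = "c1", seq_id = "chr1", start = 100,
                           end = 500, strand = "+"), "cat")
  cc2 <- classifyOverlaps(cat2, brk2)
  expect_equal(cc2$category, "one_to_many")

  ## opposite strands never connect
  brkM <- mkAnn(data.frame(gene_id = "b1", seq_id = "chr1", start = 150,
                           end = 250, strand = "-"), "braker")
  cc3 <- classifyOverlaps(catA, brkM)
  expect_setequal(cc3$category, c("cat_only", "braker_only"))
})

test_that("merge rules follow longest-CDS, cat preference and the 150-nt filter", {
  catA <- mkAnn(data.frame(gene_id = "c1", seq_id = "chr1", start = 100,
                           end = 999, strand = "+"), "cat")       # 900 bp
  brk <- mkAnn(data.frame(gene_id = "b1", seq_id = "chr1", start = 150,
                          end = 1349, strand = "+"), "braker")    # 1200 bp
  expect_equal(geneIds(mergeAnnotations(catA, brk)), "b1")

  ## equal lengths: keep cat
  brkEq <- mkAnn(data.frame(gene_id = "b1", seq_id = "chr1", start = 200,
                            end = 1099, strand = "+"), "braker")
  expect_equal(geneIds(mergeAnnotations(catA, brkEq)), "c1")

  ## 1:2 component keeps the cat gene only
  cat2 <- mkAnn(data.frame(gene_id = "c1", seq_id = "chr1", start = 100,
                           end = 500, strand = "+"), "cat")
  brk2 <- mkAnn(data.frame(gene_id = c("b1", "b2"), seq_id = "chr1",
                           start = c(100, 310), end = c(290, 500),
                           strand = "+"), "braker")
  expect_equal(geneIds(mergeAnnotations(cat2, brk2)), "c1")

  ## non-overlapping genes: strictly greater than 150 bp
  brk3 <- mkAnn(data.frame(gene_id = c("b150", "b151"), seq_id = "chr2",
                           start = c(1000, 3000),
                           end = c(1149, 3150), strand = "+"), "braker")
  merged <- mergeAnnotations(cat2, brk3)
  expect_true("b151" %in% geneIds(merged))
  expect_false("b150" %in% geneIds(merged))

  ## empty braker: merged = cat (all cat genes above the filter)
  expect_equal(geneIds(mergeAnnotations(
    cat2, mkAnn(data.frame(gene_id = character(), seq_id = character(),
                           start = integer(), end = integer(),
                           strand = character()), "braker"))), "c1")

  ## shared ids across inputs are rejected
  dup <- mkAnn(data.frame(gene_id = "c1", seq_id = "chr9", start = 1,
                          end = 300, strand = "+"), "braker")
  expect_error(mergeAnnotations(catA, dup), "namespace")
})

test_that("merge output stays within its inputs and is idempotent", {
  truth <- simAnnotation(40, seed = 51)
  pair <- simAnnotationPair(truth, simConfig(), seed = 52)
  merged <- mergeAnnotations(pair$cat, pair$braker)
  expect_lte(length(merged), length(pair$cat) + length(pair$braker))
  inputs <- c(cdsLengths(pair$cat), cdsLengths(pair$braker))
  expect_true(all(geneIds(merged) %in% names(inputs)))
  expect_equal(unname(cdsLengths(merged)),
               unname(inputs[geneIds(merged)]))
  ## merging the merged set with nothing changes nothing
  emptyB <- AnnotationSet(GenomicRanges::GRangesList(), species = "x",
                          source = "braker")
  again <- mergeAnnotations(merged, emptyB)
  expect_setequal(geneIds(again), geneIds(merged))
})

test_that("jitter-only corruption resolves every locus to one model by
           the longest-CDS rule", {
  cfg <- simConfig(pDrop = 0, pSplit = 0, pMerge = 0, pSpurious = 0,
                   jitterBp = 40L)
  for (seed in 1:10) {
    truth <- simAnnotation(30, seed = 100 + seed)
    pair <- simAnnotationPair(truth, cfg, seed = seed)
    merged <- mergeAnnotations(pair$cat, pair$braker)
    lens <- c(cdsLengths(pair$cat), cdsLengths(pair$braker))
    ## each truth gene yields a cat/braker pair still overlapping after
    ## jitter; components that are 1:1 must retain the longer model
    dec <- mergeDecisions(pair$cat, pair$braker)
    for (k in unique(dec$component[dec$category == "one_to_one"])) {
      comp <- dec[dec$component == k, ]
      expect_equal(comp$gene_id[comp$kept],
                   comp$gene_id[which.max(lens[comp$gene_id])])
    }
    ## the merged set never keeps both members of an overlapping pair
    expect_true(all(table(sub("\\.s[12]$", "",
      sub("^(cat|braker)_", "", geneIds(merged)))) <= 1) ||
      any(dec$category %in% c("many_to_many", "one_to_many",
                              "many_to_one")))
  }
})
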