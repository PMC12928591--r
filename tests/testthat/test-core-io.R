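test_that("GFF3 reading applies the longest-isoform rule and validates links", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tcat\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\tcat\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
    "chr1\tcat\tCDS\t101\t200\t.\t+\t0\tParent=t1",
    "chr1\tcat\tCDS\t301\t400\t.\t+\t2\tParent=t1",
    "chr1\tcat\tmRNA\t101\t400\t.\t+\t.\tID=t2;Parent=g1",
    "chr1\tcat\tCDS\t101\t400\t.\t+\t0\tParent=t2",
    "chr1\tcat\tCDS\t421\t570\t.\t+\t0\tParent=t2"), f)
  a <- readGFF3(f)
  ## t1 totals 200, t2 totals 450: keep t2
  expect_equal(unname(cdsLengths(a)["g1"]), 450)
  expect_equal(geneIds(a), "g1")

  f2 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr1\tcat\tgene\t1\t90\t.\t+\t.\tID=g1",
    "chr1\tcat\tCDS\t1\t90\t.\t+\t0\tParent=ghost"), f2)
  expect_error(readGFF3(f2), "ghost")
})

test_that("GFF3 writing round-trips gene structure exactly", {
  a <- randomAnnotationSet(1000, seed = 42)
  f <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(a, f)
  b <- readGFF3(f, species = "test")
  expect_setequal(geneIds(b), geneIds(a))
  expect_equal(cdsLengths(b)[geneIds(a)], cdsLengths(a))
  expect_equal(geneSources(b)[geneIds(a)], geneSources(a))
  for (id in sample(geneIds(a), 25)) {
    ga <- GenomicRanges::sort(cdsIntervals(a)[[id]])
    gb <- GenomicRanges::sort(cdsIntervals(b)[[id]])
    expect_equal(GenomicRanges::start(ga), GenomicRanges::start(gb))
    expect_equal(GenomicRanges::end(ga), GenomicRanges::end(gb))
    expect_equal(as.character(GenomicRanges::strand(ga)),
                 as.character(GenomicRanges::strand(gb)))
  }
  ## empty set: header-only file
  f0 <- withr::local_tempfile(fileext = ".gff3")
  writeGFF3(AnnotationSet(GenomicRanges::GRangesList(), species = "x"), f0)
  expect_equal(readLines(f0), "##gff-version 3")
})

test_that("extractCds splices, reverse-complements and flags frame", {
  a <- AnnotationSet(data.frame(gene_id = "g1", seq_id = "chr1",
    start = c(1, 7), end = c(3, 9), strand = "+"), species = "x")
  expect_equal(as.character(extractCds(a, c(chr1 = "ATGCCCAAA"))[[1]]),
               "ATGAAA")
  am <- AnnotationSet(data.frame(gene_id = "g1", seq_id = "chr1",
    start = 1, end = 6, strand = "-"), species = "x")
  expect_equal(as.character(extractCds(am, c(chr1 = "ATGCAT"))[[1]]),
               "ATGCAT")
  bad <- AnnotationSet(data.frame(gene_id = "g1", seq_id = "chr1",
    start = 5, end = 20, strand = "+"), species = "x")
  expect_error(extractCds(bad, c(chr1 = "ACGTACGTAC")), "bounds")
  oof <- AnnotationSet(data.frame(gene_id = "g1", seq_id = "chr1",
    start = 1, end = 4, strand = "+"), species = "x")
  expect_warning(res <- extractCds(oof, c(chr1 = "ACGTACGTAC")),
                 "divisible")
  expect_true(S4Vectors::mcols(res)$out_of_frame[1])
})

test_that("simulated genomes yield translatable CDS through extractCds", {
  ann <- simAnnotation(30, cdsLenMean = 900, seed = 7)
  gen <- simGenome(ann, seed = 8)
  cds <- extractCds(ann, gen)
  expect_false(any(S4Vectors::mcols(cds)$out_of_frame))
  aa <- as.character(Biostrings::translate(cds))
  expect_true(all(substr(aa, 1, 1) == "M"))
  internal <- vapply(strsplit(aa, ""), function(x)
    any(x[-length(x)] == "*"), TRUE)
  expect_false(any(internal))
})

test_that("readNewick validates lengths and ultrametricity", {
  f <- withr::local_tempfile()
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- readNewick(f, requireUltrametric = TRUE)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(sum(tr$edge.length), 5, tolerance = 1e-9)

  writeLines("((A:1,B:2):1,C:2);", f)
  expect_error(readNewick(f, requireUltrametric = TRUE), "ultrametric")
  expect_silent(readNewick(f))
  writeLines("(A,B);", f)
  expect_error(readNewick(f), "branch length")
})

test_that("HOG table parsing handles cells, blanks and duplicates", {
  f <- withr::local_tempfile()
  writeLines(c("HOG\tOG\tGene Tree Parent Clade\tspA\tspB",
               "N0.HOG0000001\tOG0000001\tn0\tgeneA1, geneA2\tgeneB1",
               "N0.HOG0000002\tOG0000002\tn0\t\tgeneB9"), f)
  hm <- readHogTable(f)
  m <- hogMembership(hm)
  expect_equal(sort(m$gene[m$hog == "N0.HOG0000001" & m$species == "spA"]),
               c("geneA1", "geneA2"))
  expect_equal(m$gene[m$hog == "N0.HOG0000001" & m$species == "spB"],
               "geneB1")
  ## empty cell: species absent from that HOG
  expect_false("spA" %in% m$species[m$hog == "N0.HOG0000002"])
  expect_equal(speciesUniverse(hm), c("spA", "spB"))

  writeLines(c("HOG\tOG\tGene Tree Parent Clade\tspA",
               "H1\tO1\tn0\ta1", "H1\tO1\tn0\ta2"), f)
  expect_error(readHogTable(f), "duplicate")
  writeLines(c("HOG\tOG\tGene Tree Parent Clade\tspA",
               "H1\tO1\tn0\ta1\textra\tcell"), f)
  expect_error(readHogTable(f), "ragged")
})

test_that("MSA round trip preserves case and converts frameshift marks", {
  m <- MsaBlock(c(s1 = "ATG-cc", s2 = "ATGACC"))
  f <- withr::local_tempfile(fileext = ".fa")
  writeMsa(m, f)
  m2 <- readMsa(f)
  expect_equal(msaSeqs(m2), msaSeqs(m))
  expect_equal(unname(msaSeqs(MsaBlock(c(x = "AT!")))["x"]), "ATN")
  expect_error(MsaBlock(c(s1 = "AT", s2 = "ATG")))
  expect_error(MsaBlock(c(s1 = "AXG")))
})
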