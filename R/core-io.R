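#' @include AllClasses.R
NULL

#' Read a GFF3 gene annotation into an AnnotationSet
#'
#' Parses gene/mRNA/CDS features linked through `ID`/`Parent`
#' attributes. Multi-isoform genes are collapsed to the isoform with the
#' longest summed CDS (ties broken by transcript id); coordinates are
#' kept 1-based inclusive. CDS features may be attached either to an
#' mRNA/transcript or directly to a gene.
#'
#' @param path GFF3 file.
#' @param species species identifier to record (default `NA`).
#' @return an [AnnotationSet-class].
#' @examples
#' f <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tcat\tgene\t101\t400\t.\t+\t.\tID=g1",
#'   "chr1\tcat\tmRNA\t101\t400\t.\t+\t.\tID=t1;Parent=g1",
#'   "chr1\tcat\tCDS\t101\t200\t.\t+\t0\tParent=t1",
#'   "chr1\tcat\tCDS\t301\t400\t.\t+\t2\tParent=t1"), f)
#' a <- readGFF3(f)
#' cdsLengths(a)
#' @export
readGFF3 <- function(path, species = NA_character_) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  parent <- gr$Parent                      # CharacterList
  np <- S4Vectors::elementNROWS(parent)
  parent1 <- rep(NA_character_, length(gr))
  parent1[np > 0L] <- vapply(as.list(parent[np > 0L]), `[`, "", 1L)

  isGene <- type == "gene"
  isTx <- type %in% c("mRNA", "transcript")
  isCds <- type == "CDS"
  geneIdsAll <- id[isGene]
  txId <- id[isTx]
  txParent <- parent1[isTx]
  if (anyNA(txParent) || !all(txParent %in% geneIdsAll)) {
    bad <- which(isTx)[is.na(txParent) | !(txParent %in% geneIdsAll)][1L]
    stop(sprintf("transcript feature %s (%s:%d-%d) has no parent gene",
                 id[bad] %||% "<no ID>", as.character(seqnames(gr))[bad],
                 start(gr)[bad], end(gr)[bad]))
  }
  tx2gene <- stats::setNames(txParent, txId)

  cdsParent <- parent1[isCds]
  if (anyNA(cdsParent)) {
    bad <- which(isCds)[is.na(cdsParent)][1L]
    stop(sprintf("CDS feature at %s:%d-%d has no Parent attribute",
                 as.character(seqnames(gr))[bad], start(gr)[bad],
                 end(gr)[bad]))
  }
  known <- cdsParent %in% txId | cdsParent %in% geneIdsAll
  if (!all(known)) {
    bad <- which(isCds)[!known][1L]
    stop(sprintf(
      "CDS feature at %s:%d-%d references missing Parent '%s'",
      as.character(seqnames(gr))[bad], start(gr)[bad], end(gr)[bad],
      parent1[bad]))
  }
  ## resolve every CDS to (gene, transcript); direct gene attachment gets a
  ## pseudo-transcript named after the gene
  cdsGene <- ifelse(cdsParent %in% txId, tx2gene[cdsParent], cdsParent)
  cdsTx <- cdsParent

  cds <- gr[isCds]
  if (length(cds) == 0L)
    return(AnnotationSet(GenomicRanges::GRangesList(), species = species))

  ## longest-isoform rule: per gene keep the transcript with max summed CDS
  txLen <- tapply(width(cds), cdsTx, sum)
  keepTx <- vapply(split(names(txLen), cdsGene[match(names(txLen), cdsTx)]),
                   function(txs) {
                     l <- txLen[txs]
                     txs[order(-l, txs)][1L]
                   }, "")
  sel <- cdsTx %in% keepTx
  cds <- cds[sel]
  cdsGene <- cdsGene[sel]

  src <- as.character(cds$source)
  o <- order(match(cdsGene, geneIdsAll), start(cds))
  cds <- cds[o]; cdsGene <- cdsGene[o]; src <- src[o]
  f <- factor(cdsGene, levels = unique(cdsGene))
  grl <- S4Vectors::split(granges(cds), f)
  S4Vectors::mcols(grl)$source <-
    unname(vapply(S4Vectors::split(src, f), `[`, "", 1L))
  new("AnnotationSet", species = as.character(species), genes = grl)
}

#' Write an AnnotationSet to GFF3
#'
#' Emits gene, mRNA and CDS rows with `ID`/`Parent` linkage, grouped by
#' sequence. Round-trips through [readGFF3()]: gene ids, CDS intervals,
#' strands and source tags are reproduced exactly. CDS phase is written
#' correctly but ignored by the reader (lengths come from intervals).
#'
#' @param annotation an [AnnotationSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGFF3 <- function(annotation, path) {
  stopifnot(is(annotation, "AnnotationSet"))
  validObject(annotation)
  g <- annotation@genes
  if (length(g) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  src <- geneSources(annotation)
  lines <- character()
  ord <- order(vapply(seq_along(g), function(i)
    as.character(seqnames(g[[i]]))[1L], ""),
    vapply(seq_along(g), function(i) min(start(g[[i]])), 1L))
  for (i in ord) {
    iv <- GenomicRanges::sort(g[[i]])
    gid <- names(g)[i]
    sq <- as.character(seqnames(iv))[1L]
    st <- as.character(strand(iv))[1L]
    lo <- min(start(iv)); hi <- max(end(iv))
    tid <- paste0(gid, ".t1")
    lines <- c(lines,
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s", sq, src[i], lo, hi,
              st, gid),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s", sq, src[i],
              lo, hi, st, tid, gid))
    ## phase in translation order (5' to 3')
    w <- width(iv)
    idx <- if (st == "-") rev(seq_along(iv)) else seq_along(iv)
    phase <- integer(length(iv))
    cum <- 0L
    for (k in idx) {
      phase[k] <- (3L - cum %% 3L) %% 3L
      cum <- cum + w[k]
    }
    lines <- c(lines, sprintf(
      "%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s", sq, src[i], start(iv),
      end(iv), st, phase, tid))
  }
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Extract spliced CDS sequences from a genome
#'
#' Splices each gene's CDS intervals in genomic order and
#' reverse-complements minus-strand genes so every returned sequence
#' starts with its first codon.
#'
#' @param annotation an [AnnotationSet-class].
#' @param genome named `DNAStringSet` (or named character vector) of
#'   genome sequences keyed by `seq_id`.
#' @return a `DNAStringSet` named by gene id, with a logical metadata
#'   column `out_of_frame` flagging genes whose CDS length is not a
#'   multiple of 3 (a warning is also raised for these).
#' @examples
#' df <- data.frame(gene_id = "g1", seq_id = "chr1",
#'                  start = c(1, 7), end = c(3, 9), strand = "+")
#' a <- AnnotationSet(df, species = "spA")
#' extractCds(a, c(chr1 = "ATGCCCAAA"))  # "ATGAAA"
#' @export
extractCds <- function(annotation, genome) {
  stopifnot(is(annotation, "AnnotationSet"))
  if (!is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  g <- annotation@genes
  if (length(g) == 0L)
    return(Biostrings::DNAStringSet())
  seqOf <- vapply(seq_along(g), function(i)
    as.character(seqnames(g[[i]]))[1L], "")
  missing <- setdiff(unique(seqOf), names(genome))
  if (length(missing))
    stop(sprintf("sequence '%s' not present in genome", missing[1L]))
  out <- character(length(g))
  for (i in seq_along(g)) {
    iv <- GenomicRanges::sort(g[[i]])
    sq <- genome[[seqOf[i]]]
    if (min(start(iv)) < 1L || max(end(iv)) > length(sq))
      stop(sprintf("gene '%s': CDS interval outside sequence bounds (%s has %d bp)",
                   names(g)[i], seqOf[i], length(sq)))
    pieces <- as.character(Biostrings::Views(sq, start = start(iv),
                                             end = end(iv)))
    out[i] <- paste(pieces, collapse = "")
  }
  res <- Biostrings::DNAStringSet(out)
  names(res) <- names(g)
  minus <- vapply(seq_along(g), function(i)
    as.character(strand(g[[i]]))[1L] == "-", TRUE)
  if (any(minus))
    res[minus] <- Biostrings::reverseComplement(res[minus])
  oof <- Biostrings::width(res) %% 3L != 0L
  if (any(oof))
    warning(sprintf("%d gene(s) have CDS length not divisible by 3 (e.g. '%s')",
                    sum(oof), names(res)[oof][1L]))
  S4Vectors::mcols(res)$out_of_frame <- oof
  res
}

#' Flatten an AnnotationSet to an interval table
#'
#' One row per CDS interval, 1-based inclusive coordinates — the same
#' shape the [AnnotationSet()] constructor accepts.
#'
#' @param annotation an [AnnotationSet-class].
#' @return `data.frame` with columns `gene_id`, `seq_id`, `start`,
#'   `end`, `strand`, `source`.
#' @export
annotationTable <- function(annotation) {
  g <- cdsIntervals(annotation)
  nIv <- S4Vectors::elementNROWS(g)
  unl <- unlist(g, use.names = FALSE)
  data.frame(gene_id = rep.int(names(g), nIv),
             seq_id = as.character(seqnames(unl)),
             start = start(unl), end = end(unl),
             strand = as.character(strand(unl)),
             source = rep.int(unname(geneSources(annotation)), nIv),
             stringsAsFactors = FALSE)
}

#' Read a rooted Newick tree
#'
#' @param path Newick file containing a single rooted tree with branch
#'   lengths.
#' @param requireUltrametric check that all root-to-tip path lengths are
#'   equal within `tolerance` (relative to tree depth) and error
#'   otherwise, reporting the maximum deviation.
#' @param tolerance relative ultrametricity tolerance (default 1e-6).
#' @return an `ape::phylo` tree.
#' @export
readNewick <- function(path, requireUltrametric = FALSE, tolerance = 1e-6) {
  tree <- ape::read.tree(path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("file must contain a single tree")
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("could not parse a tree from file")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicated leaf names")
  if (requireUltrametric) {
    dev <- ultrametricDeviation(tree)
    if (dev$rel > tolerance)
      stop(sprintf(
        "tree is not ultrametric: max root-to-tip deviation %.3g (depth %.3g)",
        dev$abs, dev$depth))
  }
  tree
}

## max absolute/relative root-to-tip depth deviation
ultrametricDeviation <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  list(abs = max(d) - min(d), rel = (max(d) - min(d)) / max(d),
       depth = max(d))
}

#' Read an OrthoFinder-style HOG membership table (N0.tsv dialect)
#'
#' Expects a tab-separated table whose first three columns are `HOG`,
#' `OG` and `Gene Tree Parent Clade`, followed by one column per species
#' holding comma-separated gene identifiers (possibly empty).
#'
#' @param path TSV file.
#' @return a [HogMatrix-class] over the table's species columns.
#' @export
readHogTable <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty HOG table")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  ncol <- length(header)
  if (ncol < 4L)
    stop("HOG table needs HOG, OG, clade and at least one species column")
  ## rows may drop trailing empty cells; pad those, reject longer rows
  nf <- lengths(cells[-1L])
  if (any(nf > ncol))
    stop(sprintf("ragged HOG table: row %d has %d fields, header has %d",
                 which(nf > ncol)[1L] + 1L, nf[nf > ncol][1L], ncol))
  species <- header[-(1:3)]
  if (anyDuplicated(species)) stop("duplicated species columns")
  hogs <- vapply(cells[-1L], `[`, "", 1L)
  if (anyDuplicated(hogs))
    stop(sprintf("duplicate HOG id '%s'", hogs[duplicated(hogs)][1L]))
  rows <- lapply(cells[-1L], function(x) c(x, rep("", ncol - length(x))))
  long <- list()
  for (j in seq_along(species)) {
    cell <- vapply(rows, `[`, "", j + 3L)
    has <- nzchar(trimws(cell))
    if (!any(has)) next
    genes <- strsplit(trimws(cell[has]), "\\s*,\\s*")
    long[[species[j]]] <- data.frame(
      hog = rep(hogs[has], lengths(genes)),
      species = species[j],
      gene = unlist(genes, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  membership <- if (length(long)) do.call(rbind, unname(long)) else
    data.frame(hog = character(), species = character(),
               gene = character(), stringsAsFactors = FALSE)
  HogMatrix(membership, speciesUniverse = species, hogIds = hogs)
}

#' Read an aligned FASTA into an MsaBlock
#'
#' Case is preserved (lowercase = residues masked upstream); MACSE `!`
#' frameshift characters become `N`.
#'
#' @param path aligned FASTA file.
#' @return an [MsaBlock-class].
#' @export
readMsa <- function(path) {
  s <- Biostrings::readBStringSet(path)
  MsaBlock(stats::setNames(as.character(s), names(s)))
}

#' Write an MsaBlock to aligned FASTA
#'
#' @param msa an [MsaBlock-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMsa <- function(msa, path) {
  stopifnot(is(msa, "MsaBlock"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(msa@seqs), path)
  invisible(path)
}
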