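#' @include AllClasses.R
NULL

#' The nine fully two-fold degenerate codon families
#'
#' Amino acids whose entire codon set is two-fold degenerate (Phe, Tyr,
#' His, Gln, Asn, Lys, Asp, Glu, Cys), each with its AT-ending and
#' GC-ending codon. Leu, Ser and Arg are excluded: their two-codon
#' subsets belong to six-fold families.
#'
#' @return named list (one-letter amino acid codes) of
#'   `c(at = , gc = )` codon pairs.
#' @export
twofoldFamilies <- function() {
  list(F = c(at = "TTT", gc = "TTC"), Y = c(at = "TAT", gc = "TAC"),
       H = c(at = "CAT", gc = "CAC"), Q = c(at = "CAA", gc = "CAG"),
       N = c(at = "AAT", gc = "AAC"), K = c(at = "AAA", gc = "AAG"),
       D = c(at = "GAT", gc = "GAC"), E = c(at = "GAA", gc = "GAG"),
       C = c(at = "TGT", gc = "TGC"))
}

## nitrogen and carbon atom counts of the free amino acids
## (molecular formulas, e.g. Gly C2H5NO2, Arg C6H14N4O2, Trp C11H12N2O2)
.AA_ATOMS <- data.frame(
  aa = c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
  N = c(1, 4, 2, 1, 1, 2, 1, 1, 3, 1, 1, 2, 1, 1, 1, 1, 1, 2, 1, 1),
  C = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6, 6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
  stringsAsFactors = FALSE)

## split sequences into codons; returns list(codon = chr vector,
## gene = integer index of the source gene)
.codonize <- function(cds) {
  seqs <- if (is(cds, "DNAStringSet")) as.character(cds) else
    as.character(cds)
  nCod <- nchar(seqs) %/% 3L
  big <- paste(seqs, collapse = "")
  offset <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]
  starts <- unlist(lapply(seq_along(seqs), function(i)
    offset[i] + seq(1L, by = 3L, length.out = nCod[i])), use.names = FALSE)
  list(codon = substring(big, starts, starts + 2L),
       gene = rep(seq_along(seqs), nCod))
}

## per-gene counts over a fixed codon vocabulary (genes x codons);
## in-frame trinucleotide counting done at C level by Biostrings
.geneCodonCounts <- function(cds, vocab) {
  if (!is(cds, "DNAStringSet")) cds <- Biostrings::DNAStringSet(cds)
  f <- Biostrings::oligonucleotideFrequency(cds, width = 3L, step = 3L)
  counts <- f[, vocab, drop = FALSE]
  rownames(counts) <- names(cds)
  counts
}

#' Coding-composition profile of a CDS set
#'
#' Computes GC content over all CDS bases, GC at third codon positions
#' of non-stop codons (GC3; Met and Trp third positions included, the
#' conventional definition), amino-acid frequencies from translated
#' codons (stops excluded), the usage-weighted nitrogen-to-carbon atom
#' ratio of the encoded proteome (free-amino-acid molecular formulas),
#' and the 64 codon counts. Given a genome and its annotation, also
#' computes GC over positions outside the CDS footprint.
#'
#' @param cds named `DNAStringSet` or character vector of CDS; genes
#'   whose length is not a multiple of 3 are skipped with a warning.
#' @param genome optional named `DNAStringSet` of genome sequences.
#' @param annotation optional [AnnotationSet-class] locating the CDS
#'   footprint on `genome` (required for non-coding GC).
#' @return list with elements `gc`, `gc3`, `gcNoncoding` (`NA` without
#'   genome + annotation), `aaFreqs` (20 values summing to 1),
#'   `ncRatio` and `codonCounts` (64 counts).
#' @examples
#' compositionProfile(c(g1 = "ATGGCCAAA"))$gc3   # 2/3
#' @export
compositionProfile <- function(cds, genome = NULL, annotation = NULL) {
  seqs <- if (is(cds, "DNAStringSet")) as.character(cds) else
    as.character(cds)
  if (length(seqs) == 0L) stop("empty CDS set")
  inFrame <- nchar(seqs) %% 3L == 0L
  if (!any(inFrame)) stop("no in-frame CDS")
  if (!all(inFrame))
    warning(sprintf("skipping %d CDS with length not divisible by 3",
                    sum(!inFrame)))
  seqs <- seqs[inFrame]
  cz <- .codonize(seqs)
  vocab <- .CODONS64
  codonCounts <- stats::setNames(tabulate(match(cz$codon, vocab),
                                          nbins = 64L), vocab)
  allBases <- strsplit(paste(seqs, collapse = ""), "")[[1L]]
  gc <- mean(allBases %in% c("G", "C"))
  nonStop <- !(cz$codon %in% .STOPS)
  third <- substring(cz$codon[nonStop], 3L, 3L)
  gc3 <- mean(third %in% c("G", "C"))
  aa <- Biostrings::GENETIC_CODE[cz$codon[nonStop]]
  aaFreqs <- table(factor(aa, levels = .AA_ATOMS$aa))
  aaFreqs <- as.numeric(aaFreqs) / sum(aaFreqs)
  names(aaFreqs) <- .AA_ATOMS$aa
  ncRatio <- sum(aaFreqs * .AA_ATOMS$N / .AA_ATOMS$C)
  gcNoncoding <- NA_real_
  if (!is.null(genome) && !is.null(annotation)) {
    if (!is(genome, "DNAStringSet"))
      genome <- Biostrings::DNAStringSet(genome)
    fp <- GenomicRanges::reduce(unlist(cdsIntervals(annotation),
                                       use.names = FALSE),
                                ignore.strand = TRUE)
    gcCnt <- 0; totCnt <- 0
    for (sq in names(genome)) {
      len <- length(genome[[sq]])
      cov <- IRanges::ranges(fp[GenomicRanges::seqnames(fp) == sq])
      out <- IRanges::setdiff(IRanges::IRanges(1L, len), cov)
      if (length(out) == 0L) next
      v <- Biostrings::Views(genome[[sq]], out)
      f <- colSums(Biostrings::letterFrequency(v, c("G", "C")))
      gcCnt <- gcCnt + sum(f)
      totCnt <- totCnt + sum(IRanges::width(out))
    }
    gcNoncoding <- if (totCnt > 0) gcCnt / totCnt else NA_real_
  }
  list(gc = gc, gc3 = gc3, gcNoncoding = gcNoncoding, aaFreqs = aaFreqs,
       ncRatio = ncRatio, codonCounts = codonCounts)
}

#' Bin genes into expression categories
#'
#' Sorts genes by descending expression (rank 1 = most highly
#' expressed; ties broken by gene id) and splits them into `nBins`
#' contiguous bins of near-equal size, earlier bins taking the extra
#' genes.
#'
#' @param genes character vector of gene ids.
#' @param expressionRank named numeric: rank per gene (1 = highest
#'   expression).
#' @param nBins number of bins, default 20.
#' @return named integer vector of bin indices (bin 1 = most highly
#'   expressed) with attribute `nBins`.
#' @export
binByExpression <- function(genes, expressionRank, nBins = 20L) {
  if (length(genes) < nBins) stop("fewer genes than bins")
  if (!all(genes %in% names(expressionRank)))
    stop("missing expression rank for some genes")
  r <- expressionRank[genes]
  ord <- order(r, genes)
  bins <- integer(length(genes))
  bins[ord] <- .balancedBins(length(genes), nBins)
  names(bins) <- genes
  attr(bins, "nBins") <- as.integer(nBins)
  bins
}

#' Identify optimal codons from the top expression bin
#'
#' For each fully two-fold degenerate family, the codon with the higher
#' count in the most highly expressed gene category is the optimal
#' codon; ties go to the GC-ending codon. Families with zero total
#' count are omitted with a warning.
#'
#' @param topBinCounts named numeric of codon counts in the top bin
#'   (must name both codons of each family; zero allowed).
#' @return named character vector: family (one-letter amino acid) ->
#'   optimal codon.
#' @export
identifyOptimalCodons <- function(topBinCounts) {
  fams <- twofoldFamilies()
  out <- character(0)
  dropped <- character(0)
  for (f in names(fams)) {
    at <- fams[[f]][["at"]]; gcc <- fams[[f]][["gc"]]
    if (!all(c(at, gcc) %in% names(topBinCounts)))
      stop(sprintf("counts missing for family %s", f))
    ca <- topBinCounts[[at]]; cg <- topBinCounts[[gcc]]
    if (ca + cg == 0) { dropped <- c(dropped, f); next }
    out[f] <- if (cg >= ca) gcc else at        # tie -> GC-ending
  }
  if (length(dropped))
    warning(sprintf("families with zero counts omitted: %s",
                    paste(dropped, collapse = ", ")))
  if (length(out) == 0L) stop("no usable two-fold family")
  out
}

#' Estimate the strength of selection on codon usage (S)
#'
#' Per two-fold family, `S_family` is the log-odds of optimal to
#' non-optimal codon counts in the highly expressed set minus the same
#' log-odds in the reference set, with a 0.5 pseudocount
#' (Haldane-Anscombe) added to every cell. The overall S is the mean of
#' per-family values weighted by each family's total count in the high
#' set; `aggregation = "pooled"` instead pools counts across families
#' into a single log-odds contrast.
#'
#' @param highCounts,refCounts named codon counts from disjoint highly
#'   expressed and reference gene sets.
#' @param optimal named family -> optimal codon map, as produced by
#'   [identifyOptimalCodons()].
#' @param aggregation `"weighted"` (default) or `"pooled"`.
#' @return a [CodonSelectionEstimate-class] (no bootstrap interval).
#' @examples
#' est <- estimateS(c(AAA = 30, AAG = 70), c(AAA = 50, AAG = 50),
#'                  c(K = "AAG"))
#' sValue(est)   # log(70.5/30.5) - log(50.5/50.5) = 0.838
#' @export
estimateS <- function(highCounts, refCounts, optimal,
                      aggregation = c("weighted", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (length(optimal) == 0L) stop("no usable two-fold family")
  fams <- twofoldFamilies()
  per <- lapply(names(optimal), function(f) {
    pair <- fams[[f]]
    opt <- optimal[[f]]
    non <- setdiff(pair, opt)
    gv <- function(x, codon) if (codon %in% names(x)) x[[codon]] else 0
    oh <- gv(highCounts, opt); nh <- gv(highCounts, non)
    or <- gv(refCounts, opt); nr <- gv(refCounts, non)
    data.frame(family = f, optimal = opt,
               p_high = (oh + 0.5) / (oh + nh + 1),
               p_ref = (or + 0.5) / (or + nr + 1),
               S_family = log((oh + 0.5) / (nh + 0.5)) -
                 log((or + 0.5) / (nr + 0.5)),
               weight = oh + nh,
               opt_high = oh, non_high = nh, opt_ref = or, non_ref = nr,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  S <- if (aggregation == "weighted") {
    if (sum(per$weight) == 0) stop("no counts in the high set")
    sum(per$S_family * per$weight) / sum(per$weight)
  } else {
    log((sum(per$opt_high) + 0.5) / (sum(per$non_high) + 0.5)) -
      log((sum(per$opt_ref) + 0.5) / (sum(per$non_ref) + 0.5))
  }
  new("CodonSelectionEstimate", S = S,
      perFamily = per[, c("family", "optimal", "p_high", "p_ref",
                          "S_family", "weight")],
      ciLow = NA_real_, ciHigh = NA_real_, nBoot = 0L)
}

#' Estimate S from expression-binned coding sequences
#'
#' Convenience pipeline: counts two-fold-family codons per gene,
#' identifies optimal codons from the top expression bin and contrasts
#' the top bin against the reference set (all other bins by default).
#'
#' @inheritParams bootstrapS
#' @return a [CodonSelectionEstimate-class] (no bootstrap interval).
#' @export
estimateSFromCds <- function(cds, bins,
                             refSet = c("other_bins", "all_genes"),
                             aggregation = c("weighted", "pooled")) {
  refSet <- match.arg(refSet)
  aggregation <- match.arg(aggregation)
  genes <- names(bins)
  if (is.null(genes) || !all(genes %in% names(cds)))
    stop("bins must cover genes present in 'cds'")
  fams <- twofoldFamilies()
  vocab <- as.vector(vapply(fams, identity, c(at = "", gc = "")))
  C <- .geneCodonCounts(cds[genes], vocab)
  top <- colSums(C[bins == 1L, , drop = FALSE])
  ref <- if (refSet == "other_bins")
    colSums(C[bins != 1L, , drop = FALSE]) else colSums(C)
  estimateS(top, ref, identifyOptimalCodons(top),
            aggregation = aggregation)
}

#' Bootstrap estimate of S with within-bin resampling
#'
#' Computes the point estimate of S from expression-binned coding
#' sequences (optimal codons identified from the top bin; the reference
#' set is every gene outside the top bin by default) and a percentile
#' 95% confidence interval from `nBoot` bootstrap replicates in which
#' genes are resampled with replacement within every expression bin and
#' the optimal codons are re-identified from the resampled top bin,
#' propagating identification uncertainty.
#'
#' @param cds named `DNAStringSet` or character vector of CDS.
#' @param bins bin assignment from [binByExpression()] covering the
#'   genes of `cds`.
#' @param nBoot number of bootstrap replicates (>= 2), default 1000.
#' @param seed integer seed.
#' @param refSet `"other_bins"` (all genes outside the top category,
#'   default) or `"all_genes"`.
#' @param aggregation passed to [estimateS()].
#' @return a [CodonSelectionEstimate-class] with `ciLow`, `ciHigh` and
#'   `nBoot` filled in.
#' @export
bootstrapS <- function(cds, bins, nBoot = 1000L, seed = 1L,
                       refSet = c("other_bins", "all_genes"),
                       aggregation = c("weighted", "pooled")) {
  refSet <- match.arg(refSet)
  aggregation <- match.arg(aggregation)
  if (nBoot < 2L) stop("'nBoot' must be at least 2")
  genes <- names(bins)
  if (is.null(genes) || !all(genes %in% names(cds)))
    stop("bins must cover genes present in 'cds'")
  fams <- twofoldFamilies()
  vocab <- as.vector(vapply(fams, identity, c(at = "", gc = "")))
  C <- .geneCodonCounts(cds[genes], vocab)
  nBins <- attr(bins, "nBins") %||% max(bins)

  top <- colSums(C[bins == 1L, , drop = FALSE])
  ref <- if (refSet == "other_bins")
    colSums(C[bins != 1L, , drop = FALSE]) else colSums(C)
  optimal <- identifyOptimalCodons(top)
  point <- estimateS(top, ref, optimal, aggregation = aggregation)

  idxAT <- match(vapply(fams, `[[`, "", "at"), vocab)
  idxGC <- match(vapply(fams, `[[`, "", "gc"), vocab)
  withSeed(seed, {
    topRep <- matrix(0, length(vocab), nBoot)
    refRep <- matrix(0, length(vocab), nBoot)
    for (b in seq_len(nBins)) {
      sel <- bins == b
      nb <- sum(sel)
      if (nb == 0L) next
      W <- stats::rmultinom(nBoot, nb, rep(1 / nb, nb))
      counts <- t(C[sel, , drop = FALSE]) %*% W
      if (b == 1L) {
        topRep <- topRep + counts
        if (refSet == "all_genes") refRep <- refRep + counts
      } else refRep <- refRep + counts
    }
    atH <- topRep[idxAT, , drop = FALSE]
    gcH <- topRep[idxGC, , drop = FALSE]
    atR <- refRep[idxAT, , drop = FALSE]
    gcR <- refRep[idxGC, , drop = FALSE]
    optIsGC <- gcH >= atH                      # tie -> GC-ending
    oh <- ifelse(optIsGC, gcH, atH); nh <- ifelse(optIsGC, atH, gcH)
    or <- ifelse(optIsGC, gcR, atR); nr <- ifelse(optIsGC, atR, gcR)
    usable <- (oh + nh) > 0
    if (aggregation == "weighted") {
      Sf <- log((oh + 0.5) / (nh + 0.5)) - log((or + 0.5) / (nr + 0.5))
      w <- (oh + nh) * usable
      sRep <- colSums(Sf * w) / colSums(w)
    } else {
      sRep <- log((colSums(oh * usable) + 0.5) /
                    (colSums(nh * usable) + 0.5)) -
        log((colSums(or * usable) + 0.5) / (colSums(nr * usable) + 0.5))
    }
    ci <- stats::quantile(sRep, c(0.025, 0.975), names = FALSE)
    new("CodonSelectionEstimate", S = point@S,
        perFamily = point@perFamily, ciLow = ci[1L], ciHigh = ci[2L],
        nBoot = as.integer(nBoot))
  })
}

#' Principal component analysis of amino-acid usage
#'
#' Column-centred covariance PCA (no scaling) of a species-by-amino-acid
#' frequency matrix; components are ordered by decreasing eigenvalue
#' and each component's sign is fixed so its largest-magnitude loading
#' is positive.
#'
#' @param freqMatrix numeric matrix, species x 20 amino-acid
#'   frequencies (>= 3 species).
#' @return list with `scores` (species x components), `loadings`
#'   (variables x components) and `varianceExplained` (sums to 1).
#' @export
aaPca <- function(freqMatrix) {
  x <- as.matrix(freqMatrix)
  if (nrow(x) < 3L) stop("need at least 3 species")
  if (all(abs(sweep(x, 2L, colMeans(x))) < 1e-12))
    stop("constant matrix: zero variance")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(k) {
    l <- p$rotation[, k]
    sign(l[which.max(abs(l))])
  }, 1)
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, `*`)
  loadings <- sweep(p$rotation, 2L, flip, `*`)
  ev <- p$sdev^2
  list(scores = scores, loadings = loadings,
       varianceExplained = ev / sum(ev))
}
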