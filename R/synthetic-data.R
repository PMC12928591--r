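#' @include AllClasses.R core-io.R
NULL

#' Simulation configuration
#'
#' Collects the parameters of the synthetic-data generators. Defaults
#' describe a drosophilid-like study system: a 47-My crown group,
#' genomes of about 14,549 protein-coding genes with mean CDS length
#' 1,600 bp, and moderate annotation error rates.
#'
#' @param seed integer master seed.
#' @param nSpecies number of species.
#' @param crownAge root-to-tip depth of the time tree, My.
#' @param geneCountMean mean number of genes per genome.
#' @param cdsLenMean mean CDS length, bp.
#' @param pDrop,pSplit,pMerge,pSpurious per-gene annotation corruption
#'   probabilities (drop a gene; split it into two abutting models;
#'   fuse it with its neighbour; insert a spurious short gene).
#' @param jitterBp maximum boundary jitter, bp, applied uniformly in
#'   `[-jitterBp, jitterBp]` to each outer CDS boundary.
#' @param gainRate,lossRate HOG gain and loss rates per My.
#' @param sTrue true selection coefficient on codon usage.
#' @param pRefOpt optimal-codon frequency in reference genes, in (0,1).
#' @param heritabilityTrue true phylogenetic heritability in [0,1].
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, nSpecies = 301L, crownAge = 47,
                      geneCountMean = 14549, cdsLenMean = 1600,
                      pDrop = 0.05, pSplit = 0.05, pMerge = 0.05,
                      pSpurious = 0.05, jitterBp = 30L,
                      gainRate = 0.5, lossRate = 0.01,
                      sTrue = 0.5, pRefOpt = 0.5,
                      heritabilityTrue = 0.4) {
  cfg <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
              crownAge = crownAge, geneCountMean = geneCountMean,
              cdsLenMean = cdsLenMean, pDrop = pDrop, pSplit = pSplit,
              pMerge = pMerge, pSpurious = pSpurious,
              jitterBp = as.integer(jitterBp), gainRate = gainRate,
              lossRate = lossRate, sTrue = sTrue, pRefOpt = pRefOpt,
              heritabilityTrue = heritabilityTrue)
  probs <- c(cfg$pDrop, cfg$pSplit, cfg$pMerge, cfg$pSpurious,
             cfg$pRefOpt, cfg$heritabilityTrue)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$gainRate, cfg$lossRate, cfg$crownAge, cfg$cdsLenMean) < 0))
    stop("rates and sizes must be non-negative")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate an ultrametric Yule species tree
#'
#' Pure-birth tree with `nSpecies` leaves, rescaled so the root-to-tip
#' depth is exactly `crownAge`. Leaves are labelled `s1 ... sn`.
#'
#' @param nSpecies number of leaves (>= 2).
#' @param crownAge root-to-tip depth, My.
#' @param seed integer seed; the same seed gives an identical tree.
#' @return an ultrametric `ape::phylo`.
#' @export
simTree <- function(nSpecies, crownAge = 47, seed = 1L) {
  if (nSpecies < 2L) stop("'nSpecies' must be at least 2")
  withSeed(seed, {
    tree <- ape::rphylo(nSpecies, birth = 1, death = 0)
    tree$tip.label <- paste0("s", seq_len(nSpecies))
    depth <- max(ape::node.depth.edgelength(tree)[seq_len(nSpecies)])
    tree$edge.length <- tree$edge.length * (crownAge / depth)
    tree
  })
}

## ancestor path (node ids, from the node's parent up to the root)
.ancestorPaths <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  lapply(seq_len(n + tree$Nnode), function(v) {
    path <- v
    while (v != root) { v <- parent[v]; path <- c(path, v) }
    path
  })
}

## brute-force MRCA age of a set of tip labels: walk up from the first tip
## until a node ancestral to every member is found (independent of the
## fast path used by classifyHogs)
.bruteMrcaAge <- function(tree, species, paths = .ancestorPaths(tree),
                          ages = NULL) {
  tips <- match(species, tree$tip.label)
  if (anyNA(tips)) stop("species not in tree")
  if (is.null(ages)) {
    nd <- ape::node.depth.edgelength(tree)
    ages <- max(nd[seq_len(ape::Ntip(tree))]) - nd
  }
  if (length(tips) == 1L) return(0)
  others <- lapply(paths[tips[-1L]], identity)
  for (v in paths[[tips[1L]]]) {
    if (all(vapply(others, function(p) v %in% p, TRUE))) return(ages[v])
  }
  stop("no common ancestor found")          # unreachable on a rooted tree
}

#' Simulate a HOG presence/absence matrix by gain and loss on a tree
#'
#' Gene families are born on branches at `gainRate` per My (each family
#' originating at the child node of its branch; families may also
#' originate at the root, with exposure `rootMass` My, default the tree
#' depth) and are lost independently along each descendant branch at
#' `lossRate` per My. Each surviving family contributes one gene per
#' retained species. The returned truth table carries each HOG's true
#' origin node and age plus conservation labels computed by brute force
#' from the simulation record, independently of [classifyHogs()].
#'
#' @param tree ultrametric `phylo` time tree.
#' @param gainRate,lossRate per-My rates.
#' @param seed integer seed.
#' @param rootMass exposure (My) for root-origin families; default the
#'   tree depth.
#' @param universalFrac,ancientAge,ancientMinSpecies label thresholds
#'   (matching [classifyHogs()] defaults).
#' @return `list(matrix = HogMatrix, truth = data.frame)` with truth
#'   columns `hog`, `origin_node`, `origin_age`, `n_species`,
#'   `mrca_age`, `universal`, `all_species`, `ancient`.
#' @export
simHogMatrix <- function(tree, gainRate, lossRate, seed = 1L,
                         rootMass = NULL, universalFrac = 0.99,
                         ancientAge = 50, ancientMinSpecies = 30L) {
  n <- ape::Ntip(tree)
  nd <- ape::node.depth.edgelength(tree)
  depth <- max(nd[seq_len(n)])
  ages <- depth - nd
  if (is.null(rootMass)) rootMass <- depth
  tr <- ape::reorder.phylo(tree, "cladewise")
  withSeed(seed, {
    nPerEdge <- stats::rpois(nrow(tr$edge), gainRate * tr$edge.length)
    nRoot <- stats::rpois(1L, gainRate * rootMass)
    origin <- c(rep(tr$edge[, 2L], nPerEdge), rep(n + 1L, nRoot))
    nHogs <- length(origin)
    if (nHogs == 0L)
      stop("no gene families were born; increase 'gainRate'")
    nNodes <- n + tr$Nnode
    surv <- matrix(FALSE, nNodes, nHogs)
    for (k in seq_len(nHogs)) surv[origin[k], k] <- TRUE
    pKeep <- exp(-lossRate * tr$edge.length)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      keep <- stats::runif(nHogs) < pKeep[e]
      surv[child, ] <- (surv[par, ] & keep) | surv[child, ]
    }
    pres <- surv[seq_len(n), , drop = FALSE]
    keepHog <- colSums(pres) > 0L
    pres <- pres[, keepHog, drop = FALSE]
    origin <- origin[keepHog]
    nHogs <- ncol(pres)
    hogIds <- sprintf("HOG%05d", seq_len(nHogs))

    idx <- which(pres, arr.ind = TRUE)
    sp <- tree$tip.label[idx[, 1L]]
    hog <- hogIds[idx[, 2L]]
    membership <- data.frame(hog = hog, species = sp,
                             gene = paste0("g_", hog, "_", sp),
                             stringsAsFactors = FALSE)
    mat <- HogMatrix(membership, speciesUniverse = tree$tip.label,
                     hogIds = hogIds)

    ## truth MRCA by exhaustive node scan: the youngest node whose
    ## descendant tip set contains every represented species
    ## (independent of the pairwise-MRCA path classifyHogs takes)
    desc <- matrix(FALSE, nNodes, n)
    desc[cbind(seq_len(n), seq_len(n))] <- TRUE
    for (e in rev(seq_len(nrow(tr$edge))))
      desc[tr$edge[e, 1L], ] <- desc[tr$edge[e, 1L], ] |
        desc[tr$edge[e, 2L], ]
    nSp <- colSums(pres)
    cover <- (desc * 1) %*% pres                 # nodes x HOGs
    mrca <- vapply(seq_len(nHogs), function(k) {
      if (nSp[k] == 1L) return(0)
      min(ages[cover[, k] == nSp[k]])
    }, 1)
    truth <- data.frame(
      hog = hogIds, origin_node = origin, origin_age = ages[origin],
      n_species = as.integer(nSp), mrca_age = mrca,
      universal = nSp >= ceiling(universalFrac * n),
      all_species = nSp == n,
      ancient = mrca >= ancientAge & nSp >= ancientMinSpecies,
      stringsAsFactors = FALSE)
    list(matrix = mat, truth = truth)
  })
}

#' Simulate a ground-truth gene annotation
#'
#' Lays protein-coding gene models left to right along a single
#' synthetic sequence, with gamma-distributed CDS lengths (mean
#' `cdsLenMean`), 1-5 CDS intervals per gene separated by short
#' introns, random strands and geometric intergenic gaps.
#'
#' @param nGenes number of genes.
#' @param cdsLenMean mean total CDS length, bp.
#' @param seed integer seed.
#' @param seqId sequence name (default `"chr1"`).
#' @param species species tag.
#' @return an [AnnotationSet-class] with source tag `"truth"`.
#' @export
simAnnotation <- function(nGenes, cdsLenMean = 1600, seed = 1L,
                          seqId = "chr1", species = "sim") {
  withSeed(seed, {
    rows <- vector("list", nGenes)
    pos <- 1L
    for (i in seq_len(nGenes)) {
      len <- max(93L, 3L * round(stats::rgamma(1L, shape = 4,
                                               scale = cdsLenMean / 4) / 3))
      nEx <- 1L + stats::rpois(1L, 2)
      nEx <- min(nEx, len %/% 30L)          # keep intervals comfortably long
      nEx <- max(nEx, 1L)
      cuts <- if (nEx > 1L)
        sort(sample(seq(3L, len - 3L, by = 3L), nEx - 1L)) else integer()
      sizes <- diff(c(0L, cuts, len))
      introns <- if (nEx > 1L)
        40L + stats::rgeom(nEx - 1L, 1 / 80) else integer()
      starts <- integer(nEx); ends <- integer(nEx)
      p <- pos
      for (k in seq_len(nEx)) {
        starts[k] <- p
        ends[k] <- p + sizes[k] - 1L
        p <- ends[k] + 1L + if (k < nEx) introns[k] else 0L
      }
      rows[[i]] <- data.frame(
        gene_id = sprintf("g%05d", i), seq_id = seqId,
        start = starts, end = ends,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
      pos <- max(ends) + 1L + 200L + stats::rgeom(1L, 1 / 300)
    }
    AnnotationSet(do.call(rbind, rows), species = species,
                  source = "truth")
  })
}

## stop-free codons and the genetic code, reused by several generators
.CODONS64 <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                   c("T", "C", "A", "G"), paste0),
                             c("T", "C", "A", "G"), paste0))
.STOPS <- c("TAA", "TAG", "TGA")

#' Simulate a genome sequence consistent with an annotation
#'
#' Random background bases, with each gene's spliced CDS written in as a
#' valid ORF (ATG start, stop-free interior, TAA stop) respecting
#' strand, so that [extractCds()] output always translates cleanly.
#'
#' @param annotation an [AnnotationSet-class] (single sequence).
#' @param seed integer seed.
#' @param pad extra bases after the last gene.
#' @return a named `DNAStringSet` of length 1.
#' @export
simGenome <- function(annotation, seed = 1L, pad = 100L) {
  g <- cdsIntervals(annotation)
  stopifnot(length(g) > 0L)
  seqId <- as.character(seqnames(g[[1L]]))[1L]
  total <- max(vapply(seq_along(g), function(i) max(end(g[[i]])), 1L)) + pad
  withSeed(seed, {
    genome <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    sense <- setdiff(.CODONS64, .STOPS)
    for (i in seq_along(g)) {
      iv <- GenomicRanges::sort(g[[i]])
      len <- sum(width(iv))
      if (len %% 3L != 0L) next
      nC <- len %/% 3L
      orf <- c("ATG", sample(sense, max(nC - 2L, 0L), replace = TRUE),
               if (nC >= 2L) "TAA")
      orf <- paste(orf[seq_len(nC)], collapse = "")
      chars <- strsplit(orf, "")[[1L]]
      if (as.character(strand(iv))[1L] == "-")
        chars <- rev(chartr("ACGT", "TGCA", chars))
      posv <- unlist(lapply(seq_along(iv), function(k)
        seq(start(iv)[k], end(iv)[k])))
      genome[posv] <- chars
    }
    res <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
    names(res) <- seqId
    res
  })
}

## corrupt one annotation copy; returns list(annotation, truthMap)
.corruptAnnotation <- function(truth, cfg, seed, sourceTag, prefix) {
  g <- cdsIntervals(truth)
  withSeed(seed, {
    df <- annotationTable(truth)
    df$source <- NULL
    df <- df[order(match(df$gene_id, names(g)), df$start), ]
    genes <- split(df, factor(df$gene_id, unique(df$gene_id)))
    ## 1. drop
    keep <- stats::runif(length(genes)) >= cfg$pDrop
    genes <- genes[keep]
    map <- list()
    out <- list()
    ## 2. merge adjacent pairs (same seq, same strand, genomic order)
    if (length(genes)) {
      ord <- order(vapply(genes, function(d) d$seq_id[1L], ""),
                   vapply(genes, function(d) min(d$start), 1L))
      genes <- genes[ord]
      merged <- logical(length(genes))
      i <- 1L
      while (i < length(genes)) {
        a <- genes[[i]]; b <- genes[[i + 1L]]
        if (!merged[i] && a$seq_id[1L] == b$seq_id[1L] &&
            a$strand[1L] == b$strand[1L] &&
            stats::runif(1L) < cfg$pMerge) {
          id <- paste0(prefix, "m_", a$gene_id[1L], "_", b$gene_id[1L])
          fused <- rbind(a, b)
          fused$gene_id <- id
          out[[id]] <- fused
          map[[id]] <- data.frame(derived_gene_id = id,
                                  truth_gene_id = c(a$gene_id[1L],
                                                    b$gene_id[1L]),
                                  error_mode = "merge")
          merged[i] <- merged[i + 1L] <- TRUE
          i <- i + 2L
        } else i <- i + 1L
      }
      genes <- genes[!merged]
    }
    ## 3. split
    for (d in genes) {
      tid <- d$gene_id[1L]
      L <- sum(d$end - d$start + 1L)
      if (L >= 6L && stats::runif(1L) < cfg$pSplit) {
        cut <- sample(seq(3L, L - 3L), 1L)
        cum <- cumsum(d$end - d$start + 1L)
        kcut <- which(cum >= cut)[1L]
        within <- cut - c(0L, cum)[kcut]
        d1 <- d[seq_len(kcut), , drop = FALSE]
        d2 <- d[seq(kcut, nrow(d)), , drop = FALSE]
        if (within < (d$end[kcut] - d$start[kcut] + 1L)) {
          d1$end[kcut] <- d$start[kcut] + within - 1L
          d2$start[1L] <- d$start[kcut] + within
        } else d2 <- d[seq(kcut + 1L, nrow(d)), , drop = FALSE]
        for (part in 1:2) {
          dd <- if (part == 1L) d1 else d2
          id <- paste0(prefix, tid, ".s", part)
          dd$gene_id <- id
          out[[id]] <- dd
          map[[id]] <- data.frame(derived_gene_id = id,
                                  truth_gene_id = tid,
                                  error_mode = "split")
        }
      } else {
        id <- paste0(prefix, tid)
        d$gene_id <- id
        out[[id]] <- d
        map[[id]] <- data.frame(derived_gene_id = id, truth_gene_id = tid,
                                error_mode = "intact")
      }
    }
    ## 4. boundary jitter
    if (cfg$jitterBp > 0L) {
      for (id in names(out)) {
        d <- out[[id]]
        d <- d[order(d$start), , drop = FALSE]
        j1 <- sample(seq(-cfg$jitterBp, cfg$jitterBp), 1L)
        j2 <- sample(seq(-cfg$jitterBp, cfg$jitterBp), 1L)
        ns <- max(1L, d$start[1L] + j1)
        ne <- d$end[nrow(d)] + j2
        ## keep every interval and the total CDS at least 3 bp
        ns <- min(ns, d$end[1L] - 2L)
        ne <- max(ne, d$start[nrow(d)] + 2L)
        ## a single-interval gene shrunk from both sides must keep
        ## its two boundaries from crossing (CDS stays >= 3 bp)
        if (nrow(d) == 1L) ne <- max(ne, ns + 2L)
        d$start[1L] <- ns
        d$end[nrow(d)] <- ne
        out[[id]] <- d
        map[[id]]$error_mode <- paste0(map[[id]]$error_mode, "+jitter")
      }
    }
    ## 5. spurious short genes
    nSpur <- stats::rpois(1L, cfg$pSpurious * length(g))
    if (nSpur > 0L && length(g)) {
      lim <- max(df$end)
      for (k in seq_len(nSpur)) {
        L <- sample(90:300, 1L)
        s <- sample.int(max(lim - L, 1L), 1L)
        id <- paste0(prefix, "spur", k)
        out[[id]] <- data.frame(gene_id = id, seq_id = df$seq_id[1L],
                                start = s, end = s + L - 1L,
                                strand = sample(c("+", "-"), 1L),
                                stringsAsFactors = FALSE)
        map[[id]] <- data.frame(derived_gene_id = id,
                                truth_gene_id = NA_character_,
                                error_mode = "spurious")
      }
    }
    ann <- if (length(out))
      AnnotationSet(do.call(rbind, unname(out)),
                    species = speciesName(truth), source = sourceTag)
    else AnnotationSet(GenomicRanges::GRangesList(),
                       species = speciesName(truth), source = sourceTag)
    list(annotation = ann,
         truthMap = if (length(map)) do.call(rbind, unname(map)) else
           data.frame(derived_gene_id = character(),
                      truth_gene_id = character(),
                      error_mode = character()))
  })
}

#' Simulate a pair of noisy annotations of one ground truth
#'
#' Corrupts two independent copies of a truth annotation — a
#' comparative-style copy tagged `"cat"` and a de novo-style copy
#' tagged `"braker"` — by dropping, splitting, fusing and
#' boundary-jittering gene models and inserting spurious short genes
#' (CDS 90-300 bp). The truth map records, for every derived model, the
#' truth gene(s) it came from; spurious models map to none.
#'
#' @param truth an [AnnotationSet-class] ground truth.
#' @param config a [simConfig()] list (error-rate fields are used).
#' @param seed integer seed.
#' @return `list(cat = , braker = AnnotationSet, truthMap = data.frame)`
#'   with truth-map columns `derived_gene_id`, `truth_gene_id`,
#'   `error_mode`, `copy`.
#' @export
simAnnotationPair <- function(truth, config = simConfig(), seed = 1L) {
  a <- .corruptAnnotation(truth, config, spawnSeed(seed, 1L), "cat", "cat_")
  b <- .corruptAnnotation(truth, config, spawnSeed(seed, 2L), "braker",
                          "braker_")
  a$truthMap$copy <- if (nrow(a$truthMap)) "cat" else character()
  b$truthMap$copy <- if (nrow(b$truthMap)) "braker" else character()
  list(cat = a$annotation, braker = b$annotation,
       truthMap = rbind(a$truthMap, b$truthMap))
}

#' Simulate coding sequences under selection on codon usage
#'
#' Genes are assigned evenly to `nBins` expression bins (bin 1 = most
#' highly expressed). Amino acids are drawn i.i.d. from a fixed
#' proteome-like composition. At every site belonging to one of the
#' nine fully two-fold degenerate families the designated optimal
#' (GC-ending) codon is used with probability
#' `plogis(qlogis(pRefOpt) + sTrue)` in the top bin and `pRefOpt`
#' elsewhere; all other amino acids use their synonyms uniformly.
#' Every CDS is a valid ORF (ATG start, stop-free interior, TAA stop).
#'
#' @param nGenes number of genes (>= `nBins`).
#' @param nBins number of expression bins.
#' @param sTrue true log-odds selection differential.
#' @param pRefOpt reference optimal-codon frequency in (0,1).
#' @param seed integer seed.
#' @param nCodons codons per gene including start and stop (default 510,
#'   about the drosophilid mean CDS length of 1.5-1.6 kbp).
#' @return list with elements `cds` (named `DNAStringSet`),
#'   `expression` (`data.frame` of `gene_id`, `rank`; rank 1 = highest),
#'   `optimal` (designated optimal codon per family) and `pTop` (the
#'   expected top-bin optimal-codon frequency).
#' @export
simCdsWithSelection <- function(nGenes, nBins = 20L, sTrue = 0.5,
                                pRefOpt = 0.5, seed = 1L, nCodons = 510L) {
  if (nBins < 2L) stop("'nBins' must be at least 2")
  if (nGenes < nBins) stop("fewer genes than bins")
  if (pRefOpt <= 0 || pRefOpt >= 1) stop("'pRefOpt' must be in (0,1)")
  aaFreq <- c(A = 0.078, R = 0.052, N = 0.043, D = 0.053, C = 0.019,
              Q = 0.042, E = 0.063, G = 0.072, H = 0.023, I = 0.053,
              L = 0.091, K = 0.059, M = 0.021, F = 0.039, P = 0.052,
              S = 0.068, T = 0.059, W = 0.014, Y = 0.032, V = 0.066)
  aaFreq <- aaFreq / sum(aaFreq)
  code <- Biostrings::GENETIC_CODE
  syn <- split(names(code), code)
  syn <- syn[names(aaFreq)]
  fam <- twofoldFamilies()
  optimal <- vapply(fam, function(p) p[["gc"]], "")
  pTop <- stats::plogis(stats::qlogis(pRefOpt) + sTrue)

  nInner <- nCodons - 2L
  bins <- .balancedBins(nGenes, nBins)
  ## sites are i.i.d. within a gene class, so codons can be drawn
  ## directly from a 64-codon distribution: each amino acid gets mass
  ## aaFreq, split uniformly over its synonyms except that a two-fold
  ## family splits p : (1 - p) between its optimal (GC-ending) and
  ## non-optimal codon, with p depending on the expression class
  codonProb <- function(p) {
    pr <- stats::setNames(numeric(64L), .CODONS64)
    for (a in names(aaFreq)) {
      if (a %in% names(fam)) {
        pr[fam[[a]][["gc"]]] <- aaFreq[[a]] * p
        pr[fam[[a]][["at"]]] <- aaFreq[[a]] * (1 - p)
      } else pr[syn[[a]]] <- aaFreq[[a]] / length(syn[[a]])
    }
    pr
  }
  probTop <- codonProb(pTop)
  probRef <- codonProb(pRefOpt)
  nTop <- sum(bins == 1L)
  withSeed(seed, {
    codons <- .CODONS64[c(
      sample.int(64L, nTop * nInner, replace = TRUE, prob = probTop),
      sample.int(64L, (nGenes - nTop) * nInner, replace = TRUE,
                 prob = probRef))]
    big <- paste0(codons, collapse = "")
    starts <- (seq_len(nGenes) - 1L) * (3L * nInner) + 1L
    seqs <- paste0("ATG", substring(big, starts, starts + 3L * nInner - 1L),
                   "TAA")
    ids <- sprintf("g%05d", seq_len(nGenes))
    cds <- Biostrings::DNAStringSet(seqs)
    names(cds) <- ids
    list(cds = cds,
         expression = data.frame(gene_id = ids, rank = seq_len(nGenes),
                                 stringsAsFactors = FALSE),
         optimal = optimal, pTop = pTop)
  })
}

#' Simulate species traits with known phylogenetic heritability
#'
#' Draws `y = X beta + u + e` with `u ~ N(0, h2 V A)` (A the normalized
#' phylogenetic covariance of the tree) and `e` i.i.d. with variance
#' `(1 - h2) V`.
#'
#' @param tree ultrametric `phylo`.
#' @param heritabilityTrue h2 in [0,1].
#' @param totalVariance total trait variance V.
#' @param fixedEffects optional `list(X = matrix with species rownames,
#'   beta = numeric)`.
#' @param seed integer seed.
#' @return `data.frame` with columns `species`, `trait` and any
#'   covariate columns of `X`.
#' @export
simTraits <- function(tree, heritabilityTrue, totalVariance = 1,
                      fixedEffects = NULL, seed = 1L) {
  if (heritabilityTrue < 0 || heritabilityTrue > 1)
    stop("'heritabilityTrue' must be in [0,1]")
  A <- phyloCov(tree)
  n <- nrow(A)
  mu <- rep(0, n)
  Xout <- NULL
  if (!is.null(fixedEffects)) {
    X <- as.matrix(fixedEffects$X)
    if (any(!is.finite(X))) stop("non-finite covariates")
    X <- X[rownames(A), , drop = FALSE]
    mu <- drop(X %*% fixedEffects$beta)
    Xout <- X
  }
  e <- eigen(A, symmetric = TRUE)
  withSeed(seed, {
    z <- stats::rnorm(n)
    u <- drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * z)) *
      sqrt(heritabilityTrue * totalVariance)
    eps <- stats::rnorm(n, 0, sqrt((1 - heritabilityTrue) * totalVariance))
    out <- data.frame(species = rownames(A), trait = mu + u + eps,
                      stringsAsFactors = FALSE)
    if (!is.null(Xout)) out <- cbind(out, as.data.frame(Xout))
    out
  })
}

## balanced contiguous bin sizes: earlier bins get the extra genes
.balancedBins <- function(n, nBins) {
  base <- n %/% nBins
  extra <- n %% nBins
  sizes <- rep(base, nBins) + c(rep(1L, extra), rep(0L, nBins - extra))
  rep(seq_len(nBins), sizes)
}
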