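#' @include AllClasses.R
NULL

#' @name cladecomp-accessors
#' @title Accessors for cladecomp classes
#' @description Accessor generics for the package's S4 containers.
#' @param x an object.
#' @return see the individual methods.
NULL

#' @rdname cladecomp-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("cdsLengths", function(x) standardGeneric("cdsLengths"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("geneSources", function(x) standardGeneric("geneSources"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("cdsIntervals", function(x) standardGeneric("cdsIntervals"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("hogIds", function(x) standardGeneric("hogIds"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("speciesUniverse", function(x) standardGeneric("speciesUniverse"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("hogMembership", function(x) standardGeneric("hogMembership"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("msaSeqs", function(x) standardGeneric("msaSeqs"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("sValue", function(x) standardGeneric("sValue"))

#' @rdname cladecomp-accessors
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))

## ----------------------------- AnnotationSet ------------------------------

#' @rdname cladecomp-accessors
#' @export
setMethod("geneIds", "AnnotationSet", function(x)
  if (is.null(names(x@genes))) character(0) else names(x@genes))

#' @rdname cladecomp-accessors
#' @export
setMethod("cdsLengths", "AnnotationSet", function(x) {
  len <- sum(GenomicRanges::width(x@genes))
  names(len) <- names(x@genes)
  len
})

#' @rdname cladecomp-accessors
#' @export
setMethod("geneSources", "AnnotationSet", function(x) {
  src <- S4Vectors::mcols(x@genes)$source
  names(src) <- names(x@genes)
  src
})

#' @rdname cladecomp-accessors
#' @export
setMethod("cdsIntervals", "AnnotationSet", function(x) x@genes)

#' @rdname cladecomp-accessors
#' @export
setMethod("speciesName", "AnnotationSet", function(x) x@species)

#' @rdname cladecomp-accessors
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@genes))

setMethod("show", "AnnotationSet", function(object) {
  n <- length(object@genes)
  cat(sprintf("AnnotationSet for %s: %d gene model%s\n",
              ifelse(is.na(object@species), "<unknown species>",
                     object@species), n, ifelse(n == 1L, "", "s")))
  if (n > 0L) {
    len <- cdsLengths(object)
    cat(sprintf("  sources: %s\n",
                paste(names(table(geneSources(object))), collapse = ", ")))
    cat(sprintf("  CDS length: mean %.0f bp, total %.0f bp\n",
                mean(len), sum(len)))
  }
})

#' Subset an AnnotationSet by gene id or index
#' @param x an `AnnotationSet`.
#' @param i gene ids or indices.
#' @param j,drop,... ignored.
#' @return an `AnnotationSet`.
#' @export
setMethod("[", "AnnotationSet", function(x, i, j, ..., drop = FALSE) {
  new("AnnotationSet", species = x@species, genes = x@genes[i])
})

## ------------------------------- HogMatrix --------------------------------

#' @rdname cladecomp-accessors
#' @export
setMethod("hogIds", "HogMatrix", function(x) x@hogIds)

#' @rdname cladecomp-accessors
#' @export
setMethod("speciesUniverse", "HogMatrix", function(x) x@speciesUniverse)

#' @rdname cladecomp-accessors
#' @export
setMethod("hogMembership", "HogMatrix", function(x) x@membership)

#' @rdname cladecomp-accessors
#' @export
setMethod("length", "HogMatrix", function(x) length(x@hogIds))

setMethod("show", "HogMatrix", function(object) {
  cat(sprintf("HogMatrix: %d HOGs, %d species, %d gene assignments\n",
              length(object@hogIds), length(object@speciesUniverse),
              nrow(object@membership)))
})

## -------------------------------- MsaBlock --------------------------------

#' @rdname cladecomp-accessors
#' @export
setMethod("msaSeqs", "MsaBlock", function(x) x@seqs)

#' @rdname cladecomp-accessors
#' @export
setMethod("length", "MsaBlock", function(x) length(x@seqs))

#' Alignment width (number of columns)
#' @param x an `MsaBlock`.
#' @return integer width.
#' @export
setMethod("ncol", "MsaBlock", function(x)
  if (length(x@seqs)) nchar(x@seqs[[1L]]) else 0L)

setMethod("show", "MsaBlock", function(object) {
  cat(sprintf("MsaBlock: %d sequences x %d columns\n",
              length(object@seqs), ncol(object)))
})

## ------------------------- CodonSelectionEstimate -------------------------

#' @rdname cladecomp-accessors
#' @export
setMethod("sValue", "CodonSelectionEstimate", function(x) x@S)

setMethod("show", "CodonSelectionEstimate", function(object) {
  ci <- if (object@nBoot > 0L)
    sprintf(" (95%% bootstrap CI [%.3f, %.3f], %d replicates)",
            object@ciLow, object@ciHigh, object@nBoot) else ""
  cat(sprintf("Selection on codon usage: S = %.3f%s\n", object@S, ci))
  cat(sprintf("  %d two-fold families used\n", nrow(object@perFamily)))
})

## --------------------------------- PMMFit ---------------------------------

#' @rdname cladecomp-accessors
#' @export
setMethod("heritability", "PMMFit", function(x) x@h2)

setMethod("show", "PMMFit", function(object) {
  cat(sprintf(
    "Phylogenetic mixed model fit (ML): h2 = %.3f, logLik = %.2f%s\n",
    object@h2, object@loglik,
    if (!object@identifiable) " [h2 not identifiable]" else ""))
  cat(sprintf("  sigma2_phylo = %.4g, sigma2_resid = %.4g\n",
              object@sigma2p, object@sigma2e))
  print(object@beta, row.names = FALSE)
})

setMethod("show", "BivariatePMMFit", function(object) {
  ci <- if (!is.na(object@rhoLower))
    sprintf(" (95%% profile CI [%.2f, %.2f])", object@rhoLower,
            object@rhoUpper) else ""
  cat(sprintf("Bivariate phylogenetic mixed model: rho_phylo = %.3f%s\n",
              object@rhoPhylo, ci))
  cat(sprintf("  logLik = %.2f, converged = %s\n", object@loglik,
              object@converged))
})
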