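#' @include AllClasses.R
NULL

.msaMatrix <- function(msa) {
  s <- msaSeqs(msa)
  matrix(unlist(strsplit(s, ""), use.names = FALSE),
         nrow = length(s), byrow = TRUE, dimnames = list(names(s), NULL))
}

.msaFromMatrix <- function(m) {
  MsaBlock(stats::setNames(apply(m, 1L, paste, collapse = ""),
                           rownames(m)))
}

#' Trim alignment ends by column occupancy
#'
#' From each end, removes columns while the fraction of non-gap
#' characters is below `minOccupancy`, stopping at the first column
#' whose occupancy reaches the threshold (inclusive: exactly 70%
#' occupancy stops the trim). With `codonAware = TRUE` each trim is
#' extended outward to the next multiple of 3 columns so the reading
#' frame is preserved; rounding always removes more, never restores a
#' rejected column.
#'
#' @param alignment an [MsaBlock-class].
#' @param minOccupancy minimum non-gap fraction, inclusive; default
#'   0.70.
#' @param codonAware round each trim up to whole codons (default
#'   `TRUE`).
#' @return `list(alignment = MsaBlock, report = list)` where the report
#'   gives `columns_removed_left` and `columns_removed_right`.
#' @export
trimEnds <- function(alignment, minOccupancy = 0.70, codonAware = TRUE) {
  stopifnot(is(alignment, "MsaBlock"))
  m <- .msaMatrix(alignment)
  if (ncol(m) == 0L) stop("empty alignment")
  occ <- colMeans(m != "-")
  ok <- occ >= minOccupancy
  if (!any(ok)) stop("alignment fully trimmed: no column reaches occupancy")
  left <- which(ok)[1L] - 1L
  right <- ncol(m) - which(ok)[length(which(ok))]
  if (codonAware) {
    left <- 3L * as.integer(ceiling(left / 3))
    right <- 3L * as.integer(ceiling(right / 3))
  }
  if (left + right >= ncol(m))
    stop("alignment fully trimmed: no column reaches occupancy")
  keep <- seq(left + 1L, ncol(m) - right)
  list(alignment = .msaFromMatrix(m[, keep, drop = FALSE]),
       report = list(columns_removed_left = left,
                     columns_removed_right = right))
}

#' Remove heavily masked sequences from an alignment
#'
#' Drops every row whose masked (lowercase) residues exceed `maxMasked`
#' of its non-gap residues — strictly: a row with exactly 80% masked is
#' retained. Gaps are excluded from the denominator.
#'
#' @param alignment an [MsaBlock-class] using the lowercase-masking
#'   convention.
#' @param maxMasked maximum tolerated masked fraction (exclusive);
#'   default 0.80.
#' @return `list(alignment = MsaBlock, report = list)` where the report
#'   lists `sequences_removed` (a `data.frame` of ids and masked
#'   fractions).
#' @export
dropMaskedSequences <- function(alignment, maxMasked = 0.80) {
  stopifnot(is(alignment, "MsaBlock"))
  s <- msaSeqs(alignment)
  if (length(s) == 0L) stop("empty alignment")
  nongap <- nchar(gsub("-", "", s, fixed = TRUE))
  masked <- nchar(gsub("[^acgtn]", "", s))
  frac <- ifelse(nongap > 0L, masked / nongap, 0)
  drop <- frac > maxMasked
  if (all(drop)) stop("all sequences exceed the masked-fraction threshold")
  list(alignment = MsaBlock(s[!drop]),
       report = list(sequences_removed = data.frame(
         id = names(s)[drop], masked_fraction = frac[drop],
         stringsAsFactors = FALSE)))
}
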