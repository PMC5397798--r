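# residue ordinals: k x m integer matrix, 1-based count of non-gap residues
# along each row, NA at gaps
.residueOrdinals <- function(alignment) {
  ng <- alignment@seqs != .GAP
  ord <- matrix(0L, nrow(ng), ncol(ng))
  for (s in seq_len(nrow(ng))) ord[s, ] <- cumsum(ng[s, ])
  ord[!ng] <- NA_integer_
  ord
}

# column index of each residue: k x maxOrd matrix colOf[s, ordinal]
.columnOfResidue <- function(alignment) {
  ng <- alignment@seqs != .GAP
  k <- nrow(ng)
  maxres <- max(rowSums(ng))
  out <- matrix(NA_integer_, k, maxres)
  for (s in seq_len(k)) {
    cols <- which(ng[s, ])
    out[s, seq_along(cols)] <- cols
  }
  out
}

# map computed rows onto reference rows: ungapped string first, id fallback
.matchSequences <- function(computed, reference) {
  uc <- ungappedSeqs(computed)
  ur <- ungappedSeqs(reference)
  idx <- match(uc, ur)
  dup <- duplicated(ur)
  if (any(dup[idx[!is.na(idx)]]) || anyDuplicated(stats::na.omit(idx)))
    idx[] <- NA_integer_  # ambiguous by content: fall back to ids
  if (anyNA(idx)) idx <- match(msaIDs(computed), msaIDs(reference))
  if (anyNA(idx))
    stop("sequence '", msaIDs(computed)[which(is.na(idx))[1]],
         "' has no counterpart in the reference alignment")
  if (any(ur[idx] != uc))
    stop("sequence '", msaIDs(computed)[which(ur[idx] != uc)[1]],
         "' differs from its reference counterpart")
  idx
}

#' Residue pairs aligned in core columns of a reference alignment
#'
#' A core column is one whose annotation weight is exactly 1. Every
#' unordered pair of non-gap residues co-occurring in a core column is a
#' core pair.
#'
#' @param reference a ProteinAlignment
#' @param annotation per-column coreness weights (length = column count)
#' @return data.frame with columns \code{a}, \code{b} (sequence indices,
#'   a < b), \code{ia}, \code{ib} (1-based residue ordinals), \code{column}
#' @export
corePairs <- function(reference, annotation) {
  stopifnot(length(annotation) == nColumns(reference))
  ord <- .residueOrdinals(reference)
  cols <- which(annotation == 1)
  out <- vector("list", length(cols))
  for (ci in seq_along(cols)) {
    j <- cols[ci]
    present <- which(!is.na(ord[, j]))
    if (length(present) < 2L) next
    pr <- utils::combn(present, 2L)
    out[[ci]] <- data.frame(a = pr[1L, ], b = pr[2L, ],
                            ia = ord[pr[1L, ], j], ib = ord[pr[2L, ], j],
                            column = j)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out))
    return(data.frame(a = integer(), b = integer(), ia = integer(),
                      ib = integer(), column = integer()))
  do.call(rbind, out)
}

#' True accuracy of a computed alignment
#'
#' The fraction of residue pairs aligned in core columns of the reference
#' that are also aligned (placed in a common column) in the computed
#' alignment. Defined as 1 when the reference has no core pairs.
#'
#' @param computed,reference ProteinAlignment objects over the same
#'   sequences (matched by ungapped content, falling back to ids)
#' @param annotation reference per-column coreness weights
#' @return a fraction in [0, 1]
#' @export
trueAccuracy <- function(computed, reference, annotation) {
  map <- .matchSequences(computed, reference)
  cp <- corePairs(reference, annotation)
  if (nrow(cp) == 0L) return(1)
  colOf <- .columnOfResidue(computed)
  inv <- match(seq_len(nSequences(reference)), map)  # reference row -> computed row
  ca <- colOf[cbind(inv[cp$a], cp$ia)]
  cb <- colOf[cbind(inv[cp$b], cp$ib)]
  mean(ca == cb)
}

#' True coreness of computed-alignment columns
#'
#' For a column of the computed alignment, the fraction of its non-gap
#' residue pairs that are core pairs of the reference. Columns with fewer
#' than two residues have coreness 0.
#'
#' @inheritParams trueAccuracy
#' @param columns column indices (default: all columns)
#' @return numeric vector of coreness values in [0, 1]
#' @export
trueColumnCoreness <- function(computed, reference, annotation,
                               columns = seq_len(nColumns(computed))) {
  map <- .matchSequences(computed, reference)
  ordC <- .residueOrdinals(computed)
  refColOf <- .columnOfResidue(reference)
  isCore <- annotation == 1
  out <- numeric(length(columns))
  for (ci in seq_along(columns)) {
    j <- columns[ci]
    present <- which(!is.na(ordC[, j]))
    if (length(present) < 2L) { out[ci] <- 0; next }
    # reference column holding each residue of this computed column
    rcol <- refColOf[cbind(map[present], ordC[present, j])]
    pr <- utils::combn(seq_along(present), 2L)
    same <- rcol[pr[1L, ]] == rcol[pr[2L, ]]
    core <- same & isCore[rcol[pr[1L, ]]]
    out[ci] <- mean(core)
  }
  out
}

#' Label columns core/non-core by thresholding coreness
#'
#' Strict inequality: a value exactly at the threshold is non-core.
#'
#' @param coreness numeric vector in [0,1]
#' @param threshold labeling threshold (default 0.5)
#' @return character vector over {"C", "N"}
#' @export
labelColumns <- function(coreness, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  ifelse(coreness > threshold, "C", "N")
}

#' Difficulty bin of a benchmark
#'
#' Ten equal-width bins over [0,1] by the true accuracy of the aligner's
#' default-setting alignment; half-open intervals, bin index 0..9 with
#' accuracy 1 capped into bin 9.
#'
#' @param accuracy accuracy value(s) in [0,1]
#' @return integer bin indices in 0..9
#' @export
difficultyBin <- function(accuracy) {
  stopifnot(all(accuracy >= 0 & accuracy <= 1))
  pmin(as.integer(floor(accuracy * 10)), 9L)
}
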