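# Amino-acid equivalence classes for the Amino Acid Identity feature.
.AI_CLASSES <- c(L = "LVIM", V = "LVIM", I = "LVIM", M = "LVIM",
                 C = "C", A = "A", G = "G", S = "ST", T = "ST", P = "P",
                 F = "FYW", Y = "FYW", W = "FYW",
                 E = "EDNQ", D = "EDNQ", N = "EDNQ", Q = "EDNQ",
                 K = "KR", R = "KR", H = "H")

# representatives for ambiguity codes in residue-pair scoring
.AMBIG_REP <- c(B = "N", Z = "Q", U = "C", O = "K")

.FEATURES <- c("F_AC", "F_SI_aug", "F_BL_aug", "F_AI_aug", "F_AS_aug",
               "F_SI", "F_BL", "F_AI", "F_AS", "F_SA", "F_GO", "F_GE")

#' Pairwise sequence statistics for the core-column normalizer
#'
#' Length aggregates and averaged pairwise ratios of the (ungapped) input
#' sequences: percent-identity-like ratios p (longest-common-subsequence
#' length over the pair's min/avg/max length), length quotients q (pair
#' min/avg over pair max), and relative length differences r (|difference|
#' over pair min/avg).
#'
#' @param seqs character vector of ungapped sequences (or a
#'   ProteinAlignment, whose rows are degapped first)
#' @return named list: lmin, lavg, lmax, pmin, pavg, pmax, qmin, qavg,
#'   rmin, ravg
#' @export
sequenceStats <- function(seqs) {
  if (is(seqs, "ProteinAlignment")) seqs <- ungappedSeqs(seqs)
  stopifnot(length(seqs) >= 2L)
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  len <- nchar(seqs)
  pr <- utils::combn(length(seqs), 2L)
  la <- len[pr[1L, ]]; lb <- len[pr[2L, ]]
  # LCS length via weighted edit distance: substitutions cost 2, so
  # d = la + lb - 2 * LCS
  d <- vapply(seq_len(ncol(pr)), function(t)
    utils::adist(seqs[pr[1L, t]], seqs[pr[2L, t]],
                 costs = list(ins = 1, del = 1, sub = 2))[1L, 1L],
    numeric(1))
  lcs <- (la + lb - d) / 2
  pmn <- pmin(la, lb); pmx <- pmax(la, lb); pav <- (la + lb) / 2
  list(lmin = min(len), lavg = mean(len), lmax = max(len),
       pmin = mean(lcs / pmn), pavg = mean(lcs / pav),
       pmax = mean(lcs / pmx),
       qmin = mean(pmn / pmx), qavg = mean(pav / pmx),
       rmin = mean(abs(la - lb) / pmn), ravg = mean(abs(la - lb) / pav))
}

# the 72 candidate normalizer terms: one length aggregate times at most two
# ratios from distinct groups (identity p, quotient q, relative difference r)
.normalizerTerms <- function() {
  lens <- c("lmin", "lavg", "lmax")
  grp <- list(p = c("pmin", "pavg", "pmax"), q = c("qmin", "qavg"),
              r = c("rmin", "ravg"))
  ratios <- unlist(grp, use.names = FALSE)
  twos <- c(as.vector(outer(grp$p, grp$q, paste, sep = "*")),
            as.vector(outer(grp$p, grp$r, paste, sep = "*")),
            as.vector(outer(grp$q, grp$r, paste, sep = "*")))
  unlist(lapply(lens, function(l) c(l, paste(l, ratios, sep = "*"),
                                    paste(l, twos, sep = "*"))))
}

.termValue <- function(term, stats) {
  prod(vapply(strsplit(term, "*", fixed = TRUE)[[1L]],
              function(f) stats[[f]], numeric(1)))
}

#' Default (fitted) core-column-count normalizer
#'
#' The shipped coefficients of the normalizer L(S) for the Predicted
#' Alignment Coreness feature.
#' @return a \linkS4class{NormalizerModel}
#' @export
defaultNormalizer <- function() {
  new("NormalizerModel", coefficients = c(
    "lmin*pmax*qmin" = 1.020, "lmin*qmin" = 0.151,
    "lavg*pmax*qavg" = 0.035, "lavg*pmin*rmin" = 0.032,
    "lmax*pavg*ravg" = 0.003))
}

#' Evaluate a normalizer on sequence statistics
#'
#' @param model a \linkS4class{NormalizerModel}
#' @param stats result of \code{\link{sequenceStats}}
#' @return the estimated number of core columns
#' @export
normalizerValue <- function(model, stats) {
  cf <- model@coefficients
  sum(cf * vapply(names(cf), .termValue, numeric(1), stats = stats))
}

#' Fit the core-column-count normalizer
#'
#' Linear program minimizing the L1 norm between the linear combination of
#' candidate terms and the true core-column counts, with non-negative
#' coefficients over the 72-term candidate set.
#'
#' @param statsList list of \code{\link{sequenceStats}} results, one per
#'   training benchmark
#' @param coreCounts true core-column count per benchmark
#' @return a \linkS4class{NormalizerModel} (zero coefficients dropped)
#' @export
fitNormalizer <- function(statsList, coreCounts) {
  stopifnot(length(statsList) == length(coreCounts),
            length(statsList) >= 2L)
  terms <- .normalizerTerms()
  X <- t(vapply(statsList, function(s)
    vapply(terms, .termValue, numeric(1), stats = s), numeric(length(terms))))
  n <- nrow(X); p <- ncol(X)
  # variables: coefficients (p), residual bounds u (n); min sum(u)
  # rows:  X c - u <= y   and   -X c - u <= -y
  ij <- which(X != 0, arr.ind = TRUE)
  i <- c(ij[, 1L], ij[, 1L] + n, seq_len(n), seq_len(n) + n)
  j <- c(ij[, 2L], ij[, 2L], p + seq_len(n), p + seq_len(n))
  v <- c(X[ij], -X[ij], rep(-1, 2L * n))
  b <- c(coreCounts, -coreCounts)
  obj <- c(numeric(p), rep(1, n))
  sol <- .solveLP(i, j, v, b, obj, nRows = 2L * n, nCols = p + n)
  cf <- sol$x[seq_len(p)]
  cf[cf < 1e-10] <- 0
  names(cf) <- terms
  new("NormalizerModel", coefficients = cf[cf > 0])
}

## ---- per-alignment feature machinery -------------------------------------

# argmax secondary-structure state per residue, as a k x m matrix (NA at
# gaps); ties go to the first of H, E, C
.ssArgmaxMatrix <- function(alignment, ss) {
  validateSS(alignment, ss)
  k <- nSequences(alignment); m <- nColumns(alignment)
  out <- matrix(NA_character_, k, m)
  ord <- .residueOrdinals(alignment)
  for (s in seq_len(k)) {
    conf <- ss[[msaIDs(alignment)[s]]]
    st <- .SS3[max.col(conf, ties.method = "first")]
    ng <- which(!is.na(ord[s, ]))
    out[s, ng] <- st[ord[s, ng]]
  }
  out
}

.choose2 <- function(n) n * (n - 1) / 2

.blosumRescaled <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  s <- e$BLOSUM62[.AA20, .AA20]
  (s - min(s)) / (max(s) - min(s))
}

# per-column match/total pair counts for an identity-type feature
.identityColumns <- function(charMat) {
  m <- ncol(charMat)
  match <- numeric(m); total <- numeric(m)
  for (j in seq_len(m)) {
    v <- charMat[, j]
    v <- v[!is.na(v)]
    total[j] <- .choose2(length(v))
    if (length(v) >= 2L)
      match[j] <- sum(.choose2(table(v)))
  }
  list(match = match, total = total)
}

.ratioFeature <- function(num, den, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(num))
  dn <- sum(den * weights)
  if (dn <= 0) 0 else sum(num * weights) / dn
}

#' Gap features of an alignment
#'
#' Gap Extension Density: the fraction of alignment entries that are gaps.
#' Gap Open Density: the fraction of gap characters that start a gap run.
#'
#' @param alignment a ProteinAlignment
#' @return named vector c(F_GO, F_GE)
#' @export
featureGaps <- function(alignment) {
  g <- alignment@seqs == .GAP
  nGaps <- sum(g)
  if (nGaps == 0L) return(c(F_GO = 0, F_GE = 0))
  starts <- g & !cbind(FALSE, g[, -ncol(g), drop = FALSE])
  c(F_GO = sum(starts) / nGaps, F_GE = nGaps / length(g))
}

#' Secondary Structure Agreement
#'
#' For every residue pair in a column, the probability that the two
#' residues share a secondary-structure state (dot product of their
#' confidence triples), averaged over a +/-2 window that follows each
#' residue along its own sequence with weights (1,2,4,2,1)/10 (weights of
#' offsets that run off a sequence end are dropped and the rest
#' renormalized), then averaged over all pairs.
#'
#' @param alignment a ProteinAlignment
#' @param ss per-sequence confidences
#' @return F_SA in [0, 1]
#' @export
featureSSAgreement <- function(alignment, ss) {
  validateSS(alignment, ss)
  k <- nSequences(alignment)
  ord <- .residueOrdinals(alignment)
  ids <- msaIDs(alignment)
  wts <- c(1, 2, 4, 2, 1) / 10
  total <- 0; count <- 0
  for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
    J <- which(!is.na(ord[a, ]) & !is.na(ord[b, ]))
    if (!length(J)) next
    o1 <- ord[a, J]; o2 <- ord[b, J]
    c1 <- ss[[ids[a]]]; c2 <- ss[[ids[b]]]
    num <- numeric(length(J)); den <- numeric(length(J))
    for (t in seq_along(wts)) {
      off <- t - 3L
      ok <- o1 + off >= 1L & o1 + off <= nrow(c1) &
            o2 + off >= 1L & o2 + off <= nrow(c2)
      if (!any(ok)) next
      agree <- rowSums(c1[o1[ok] + off, , drop = FALSE] *
                       c2[o2[ok] + off, , drop = FALSE])
      num[ok] <- num[ok] + wts[t] * agree
      den[ok] <- den[ok] + wts[t]
    }
    total <- total + sum(num / den)
    count <- count + length(J)
  }
  if (count == 0L) 0 else total / count
}

#' Identity-family features
#'
#' Secondary Structure Identity (fraction of column residue pairs sharing
#' the same predicted structure type), Amino Acid Identity (sharing the
#' same amino-acid equivalence class), and Average Substitution Score
#' (mean [0,1]-rescaled BLOSUM62 score over column residue pairs), plus
#' their coreness-augmented versions: both the per-column numerator and
#' denominator terms are multiplied by the column's coreness weight.
#'
#' @param alignment a ProteinAlignment
#' @param ss per-sequence confidences
#' @param weights per-column coreness weights in [0,1], or NULL for the
#'   unaugmented values only
#' @return named vector with F_SI, F_AI, F_AS and (when weights are given)
#'   F_SI_aug, F_AI_aug, F_AS_aug
#' @export
featureIdentityFamily <- function(alignment, ss, weights = NULL) {
  A <- .ssArgmaxMatrix(alignment, ss)
  si <- .identityColumns(A)
  chars <- alignment@seqs
  chars[chars == .GAP] <- NA_character_
  aiMat <- matrix(.AI_CLASSES[chars], nrow(chars), ncol(chars))
  aiMat[!is.na(chars) & is.na(aiMat)] <- chars[!is.na(chars) & is.na(aiMat)]
  ai <- .identityColumns(aiMat)
  # average substitution score per column
  bl <- .blosumRescaled()
  rep_ <- chars
  for (code in names(.AMBIG_REP)) rep_[rep_ == code] <- .AMBIG_REP[[code]]
  rep_[!is.na(rep_) & !(rep_ %in% .AA20)] <- NA_character_
  m <- ncol(chars)
  asNum <- numeric(m); asDen <- numeric(m)
  for (j in seq_len(m)) {
    v <- rep_[, j]; v <- v[!is.na(v)]
    asDen[j] <- .choose2(length(v))
    if (length(v) >= 2L) {
      pr <- utils::combn(v, 2L)
      asNum[j] <- sum(bl[cbind(pr[1L, ], pr[2L, ])])
    }
  }
  out <- c(F_SI = .ratioFeature(si$match, si$total),
           F_AI = .ratioFeature(ai$match, ai$total),
           F_AS = .ratioFeature(asNum, asDen))
  if (!is.null(weights)) {
    stopifnot(length(weights) == m)
    out <- c(out,
             F_SI_aug = .ratioFeature(si$match, si$total, weights),
             F_AI_aug = .ratioFeature(ai$match, ai$total, weights),
             F_AS_aug = .ratioFeature(asNum, asDen, weights))
  }
  out
}

#' Secondary Structure Blockiness
#'
#' Maximum total score of a packing of secondary-structure blocks: a block
#' is a column interval together with at least two sequences that are
#' gap-free and share one predicted structure type throughout the
#' interval; a packing uses disjoint intervals; the score of a block is its
#' residue-pair count (per column, optionally weighted by the column's
#' coreness). Normalized by the total (weighted) residue-pair count over
#' all columns. Solved exactly by dynamic programming over column
#' intervals.
#'
#' @param alignment a ProteinAlignment
#' @param ss per-sequence confidences
#' @param weights per-column coreness weights (NULL for unaugmented only)
#' @param minWidth minimum block width in columns
#' @return named vector with F_BL (and F_BL_aug when weights are given)
#' @export
featureBlockiness <- function(alignment, ss, weights = NULL, minWidth = 1L) {
  A <- .ssArgmaxMatrix(alignment, ss)
  k <- nrow(A); m <- ncol(A)
  pairCount <- vapply(seq_len(m), function(j) .choose2(sum(!is.na(A[, j]))),
                      numeric(1))
  pack <- function(w) {
    best <- numeric(m + 1L)
    cum <- cumsum(c(0, w))
    for (j in seq_len(m)) {
      best[j + 1L] <- best[j]
      for (s in .SS3) {
        elig <- !is.na(A[, j]) & A[, j] == s
        i <- j
        while (i >= 1L) {
          if (i < j) elig <- elig & !is.na(A[, i]) & A[, i] == s
          r <- sum(elig)
          if (r < 2L) break
          if (j - i + 1L >= minWidth) {
            cand <- best[i] + .choose2(r) * (cum[j + 1L] - cum[i])
            if (cand > best[j + 1L]) best[j + 1L] <- cand
          }
          i <- i - 1L
        }
      }
    }
    den <- sum(pairCount * w)
    if (den <= 0) 0 else best[m + 1L] / den
  }
  out <- c(F_BL = pack(rep(1, m)))
  if (!is.null(weights)) {
    stopifnot(length(weights) == m)
    out <- c(out, F_BL_aug = pack(weights))
  }
  out
}

#' Predicted Alignment Coreness
#'
#' The number of columns whose window's predicted coreness reaches the
#' threshold kappa, normalized by the estimated number of core columns in
#' the (unknown) reference alignment of the same sequences. Every column
#' yields a window (edges padded), so the count ranges over all columns.
#'
#' @param coreness per-column (predicted) coreness values
#' @param stats \code{\link{sequenceStats}} of the alignment's sequences
#' @param kappa counting threshold in [0, 1]
#' @param normalizer a \linkS4class{NormalizerModel}
#' @return F_AC (non-negative; may exceed 1)
#' @export
featureAlignmentCoreness <- function(coreness, stats, kappa = 0.5,
                                     normalizer = defaultNormalizer()) {
  stopifnot(kappa >= 0, kappa <= 1)
  L <- normalizerValue(normalizer, stats)
  sum(coreness >= kappa) / L
}

#' All estimator features of an alignment
#'
#' Computes the full feature vector: Predicted Alignment Coreness, the
#' coreness-augmented and plain identity-family and blockiness features,
#' secondary-structure agreement, and the gap densities. Column coreness
#' weights come from \code{coreness} if given, else from the regressor's
#' predictions; with neither, the coreness-dependent features are NA.
#'
#' @param alignment a ProteinAlignment
#' @param ss per-sequence confidences
#' @param coreness optional per-column coreness weights (e.g. true
#'   coreness)
#' @param regressor optional \linkS4class{CorenessRegressor}
#' @param kappa threshold for the coreness count feature
#' @param normalizer \linkS4class{NormalizerModel} for F_AC
#' @return named numeric vector over the 12 features
#' @export
computeFeatures <- function(alignment, ss, coreness = NULL, regressor = NULL,
                            kappa = 0.5, normalizer = defaultNormalizer()) {
  if (is.null(coreness) && !is.null(regressor))
    coreness <- predictAlignment(regressor, alignment, ss)
  idf <- featureIdentityFamily(alignment, ss, weights = coreness)
  blk <- featureBlockiness(alignment, ss, weights = coreness)
  gaps <- featureGaps(alignment)
  fsa <- featureSSAgreement(alignment, ss)
  fac <- if (is.null(coreness)) NA_real_ else
    featureAlignmentCoreness(coreness, sequenceStats(alignment),
                             kappa = kappa, normalizer = normalizer)
  out <- stats::setNames(rep(NA_real_, length(.FEATURES)), .FEATURES)
  out["F_AC"] <- fac
  out[names(idf)] <- idf
  out[names(blk)] <- blk
  out[names(gaps)] <- gaps
  out["F_SA"] <- fsa
  out
}

#' Default (fitted) accuracy estimator coefficients
#' @return an \linkS4class{EstimatorModel}
#' @export
defaultEstimator <- function() {
  new("EstimatorModel", coefficients = c(
    F_SI_aug = 0.656, F_BL_aug = 0.128, F_SA = 0.123, F_SI = 0.089,
    F_BL = 0.064, F_AC = 0.015, F_GE = 0.007, F_GO = 0.006))
}

#' Estimate alignment accuracy from features
#'
#' Dot product of the estimator's coefficients with the corresponding
#' feature values.
#'
#' @param model an \linkS4class{EstimatorModel}
#' @param features named feature vector (from \code{\link{computeFeatures}})
#' @return estimated accuracy (non-negative real)
#' @export
estimateAccuracy <- function(model, features) {
  cf <- model@coefficients
  miss <- setdiff(names(cf), names(features))
  if (length(miss))
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  v <- features[names(cf)]
  if (anyNA(v))
    stop("feature(s) unavailable (NA): ",
         paste(names(cf)[is.na(v)], collapse = ", "))
  sum(cf * v)
}

#' Fit estimator coefficients from benchmarks
#'
#' Non-negative least squares of within-benchmark true-accuracy differences
#' on feature differences over all alignment pairs of each benchmark
#' (pairs oriented so the accuracy difference is non-negative). This
#' targets the ranking behavior an advisor needs.
#'
#' @param features numeric matrix, one row per computed alignment, named
#'   feature columns
#' @param accuracy true accuracy per row
#' @param benchmark benchmark id per row (pairs are formed within ids)
#' @return an \linkS4class{EstimatorModel}
#' @export
fitEstimator <- function(features, accuracy, benchmark) {
  stopifnot(nrow(features) == length(accuracy),
            length(accuracy) == length(benchmark))
  Xd <- list(); yd <- list()
  for (bid in unique(benchmark)) {
    rows <- which(benchmark == bid)
    if (length(rows) < 2L) next
    pr <- utils::combn(rows, 2L)
    dy <- accuracy[pr[1L, ]] - accuracy[pr[2L, ]]
    dX <- features[pr[1L, ], , drop = FALSE] -
          features[pr[2L, ], , drop = FALSE]
    flip <- dy < 0
    dy[flip] <- -dy[flip]
    dX[flip, ] <- -dX[flip, , drop = FALSE]
    Xd[[length(Xd) + 1L]] <- dX
    yd[[length(yd) + 1L]] <- dy
  }
  if (!length(Xd))
    stop("need at least one benchmark with two or more alignments")
  X <- do.call(rbind, Xd); y <- unlist(yd)
  fit <- pracma::lsqnonneg(X, y)
  cf <- fit$x
  names(cf) <- colnames(features)
  cf[cf < 1e-10] <- 0
  new("EstimatorModel", coefficients = cf)
}

#' Pick the alignment of highest estimated accuracy
#'
#' @param scores estimator values of the candidate alignments
#' @return 1-based index of the chosen candidate (ties: lowest index)
#' @export
advise <- function(scores) {
  stopifnot(length(scores) >= 1L)
  which.max(scores)
}

#' Advising accuracy, averaged within and then across difficulty bins
#'
#' For each benchmark the advisor picks the candidate of highest estimated
#' accuracy; the picked candidates' true accuracies are averaged within
#' each difficulty bin, and the final score is the mean over non-empty
#' bins (so easy benchmarks cannot swamp hard ones).
#'
#' @param trueAcc matrix of true accuracies (benchmarks x candidates)
#' @param estimates matrix of estimator values, same shape
#' @param bins difficulty bin per benchmark (see \code{\link{difficultyBin}})
#' @return list: \code{picks}, \code{advisedAccuracy}, \code{perBin}
#'   (named bin means), \code{score} (mean of bin means)
#' @export
evaluateAdvising <- function(trueAcc, estimates, bins) {
  stopifnot(all(dim(trueAcc) == dim(estimates)),
            nrow(trueAcc) == length(bins))
  picks <- apply(estimates, 1L, advise)
  got <- trueAcc[cbind(seq_len(nrow(trueAcc)), picks)]
  perBin <- tapply(got, factor(bins), mean)
  list(picks = picks, advisedAccuracy = got,
       perBin = perBin, score = mean(perBin))
}

setMethod("show", "EstimatorModel", function(object) {
  cat("EstimatorModel:\n")
  cf <- object@coefficients[object@coefficients > 0]
  for (nm in names(cf)) cat(sprintf("  %8.4f  %s\n", cf[[nm]], nm))
})

setMethod("show", "NormalizerModel", function(object) {
  cat("NormalizerModel:\n")
  cf <- object@coefficients[object@coefficients > 0]
  for (nm in names(cf)) cat(sprintf("  %8.4f  %s\n", cf[[nm]], nm))
})
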