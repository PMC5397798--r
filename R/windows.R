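# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Profile matrix of an alignment
#'
#' Column profiles over the alphabet's states: for non-gap state (a, s) the
#' profile value is the sum over residues with amino acid a of their
#' secondary-structure confidence for s, divided by the number of sequences;
#' the gap state gets the column's gap frequency. Every column sums to 1.
#' Ambiguity codes (when permitted by the alignment) are expanded to a
#' uniform distribution over their residue expansion.
#'
#' @param alignment a ProteinAlignment
#' @param ss named list of per-sequence confidence matrices (rows = non-gap
#'   residues, columns H, E, C)
#' @param alphabet a StateAlphabet
#' @return numeric matrix nStates x nColumns
#' @export
profileMatrix <- function(alignment, ss, alphabet = stateAlphabet("full")) {
  validateSS(alignment, ss)
  k <- nSequences(alignment)
  m <- nColumns(alignment)
  ns <- nStates(alphabet)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (s in seq_len(k)) {
    id <- msaIDs(alignment)[s]
    row <- alignment@seqs[s, ]
    cols <- which(row != .GAP)
    if (!length(cols)) next
    conf <- ss[[id]]
    letters <- row[cols]
    for (ord in seq_along(cols)) {
      lt <- letters[ord]
      members <- if (lt %in% .AA20) lt else .AMBIG[[lt]]
      wgt <- 1 / (k * length(members))
      gidx <- match(alphabet@groups[members], alphabet@residues)
      for (ssi in 1:3) {
        ii <- c(ii, (gidx - 1L) * 3L + ssi)
        jj <- c(jj, rep(cols[ord], length(gidx)))
        xx <- c(xx, rep(conf[ord, ssi] * wgt, length(gidx)))
      }
    }
  }
  M <- as.matrix(Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ns, m)))
  M[ns, ] <- colMeans(alignment@seqs == .GAP)
  dimnames(M) <- list(alphabet@states, NULL)
  M
}

#' Profile of a single column
#'
#' @param residues character vector of the column's characters ('-' for gaps)
#' @param conf numeric matrix with one (H, E, C) confidence row per non-gap
#'   residue, in column order
#' @param alphabet a StateAlphabet
#' @return numeric vector over states, summing to 1
#' @export
columnProfile <- function(residues, conf, alphabet = stateAlphabet("full")) {
  k <- length(residues)
  ng <- which(residues != .GAP)
  if (NROW(conf) != length(ng))
    stop("need one confidence triple per non-gap residue (",
         length(ng), " residues, ", NROW(conf), " rows)")
  ns <- nStates(alphabet)
  prof <- numeric(ns)
  names(prof) <- alphabet@states
  conf <- matrix(conf, ncol = 3L)
  conf <- conf / rowSums(conf)
  for (r in seq_along(ng)) {
    lt <- residues[ng[r]]
    members <- if (lt %in% .AA20) lt else .AMBIG[[lt]]
    gidx <- match(alphabet@groups[members], alphabet@residues)
    for (ssi in 1:3) {
      at <- (gidx - 1L) * 3L + ssi
      prof[at] <- prof[at] + conf[r, ssi] / (k * length(members))
    }
  }
  prof[ns] <- (k - length(ng)) / k
  prof
}

#' Extract one window per alignment column
#'
#' Windows cover 2w+1 consecutive columns centered on each column; columns
#' beyond either edge are padded with pure-gap-state profiles.
#'
#' @param alignment a ProteinAlignment
#' @param ss per-sequence confidence matrices
#' @param w window half-width (>= 1)
#' @param alphabet StateAlphabet
#' @return a \linkS4class{WindowSet} with one window per column
#' @export
extractWindows <- function(alignment, ss, w = 1L,
                           alphabet = stateAlphabet("full")) {
  stopifnot(w >= 1L)
  w <- as.integer(w)
  P <- profileMatrix(alignment, ss, alphabet)
  ns <- nStates(alphabet)
  m <- ncol(P)
  gapProf <- numeric(ns); gapProf[ns] <- 1
  PM <- cbind(matrix(gapProf, ns, w), P, matrix(gapProf, ns, w))
  blocks <- lapply(seq_len(2L * w + 1L), function(o) t(PM[, o + 0:(m - 1L), drop = FALSE]))
  profiles <- do.call(cbind, blocks)
  new("WindowSet", profiles = profiles, width = w, alphabet = alphabet,
      info = data.frame(column = seq_len(m)))
}

#' Class of a labeled window
#'
#' For width 1, the label string itself: core classes CCC, CCN, NCC;
#' structured non-core CNN, NNC; unstructured NNN. The patterns NCN and CNC
#' are excluded (returned as "excluded"). Wider windows are classified by
#' the center column and its two immediate flanks (the center-run
#' structure), so the same six classes apply for any width.
#'
#' @param labels character vector over {"C","N"} of odd length >= 3
#' @return one of "CCC","CCN","NCC","CNN","NNC","NNN" or "excluded"
#' @export
windowClass <- function(labels) {
  n <- length(labels)
  stopifnot(n >= 3L, n %% 2L == 1L, all(labels %in% c("C", "N")))
  mid <- (n + 1L) %/% 2L
  key <- paste(labels[(mid - 1L):(mid + 1L)], collapse = "")
  if (key %in% .EXCLUDED_PATTERNS) "excluded" else key
}

#' @rdname windowClass
#' @param x a WindowSet
#' @export
windowClasses <- function(x) x@info$class

# label vector -> per-column class (edges padded with N)
.columnClasses <- function(labels) {
  lab <- c("N", labels, "N")
  vapply(seq_along(labels), function(j) windowClass(lab[j:(j + 2L)]), "")
}

#' Labeled windows of a benchmark
#'
#' Extracts windows from a benchmark's computed alignments (and/or its
#' reference alignment), attaching per-column true coreness, the core/
#' non-core label obtained by thresholding coreness, and the window class.
#' Flank labels beyond the alignment edge count as non-core.
#'
#' @param benchmark a benchmark as returned by \code{\link{loadBenchmark}}
#'   or \code{\link{generateBenchmark}}
#' @param w window half-width
#' @param alphabet StateAlphabet
#' @param threshold coreness threshold for the core label (strict >)
#' @param source take windows from "computed" alignments, the "reference",
#'   or "both"
#' @param id benchmark identifier recorded in the window metadata
#' @return a \linkS4class{WindowSet}; excluded-pattern windows carry class NA
#' @export
benchmarkWindows <- function(benchmark, w = 1L,
                             alphabet = stateAlphabet("full"),
                             threshold = 0.5,
                             source = c("computed", "reference", "both"),
                             id = "bench") {
  source <- match.arg(source)
  pieces <- list()
  addPiece <- function(aln, coreness, src, alnid) {
    ws <- extractWindows(aln, benchmark$ss, w, alphabet)
    labels <- labelColumns(coreness, threshold)
    cls <- .columnClasses(labels)
    cls[cls == "excluded"] <- NA_character_
    ws@info <- data.frame(benchmark = id, alignment = alnid,
                          column = ws@info$column, coreness = coreness,
                          label = labels, class = cls, source = src)
    pieces[[length(pieces) + 1L]] <<- ws
  }
  if (source %in% c("computed", "both")) {
    for (aid in names(benchmark$computed)) {
      comp <- benchmark$computed[[aid]]
      cor <- trueColumnCoreness(comp, benchmark$reference,
                                benchmark$annotation)
      addPiece(comp, cor, "computed", aid)
    }
  }
  if (source %in% c("reference", "both"))
    addPiece(benchmark$reference, benchmark$annotation, "reference", "ref")
  bindWindows(pieces)
}

#' Concatenate window sets
#' @param sets list of WindowSet objects sharing width and alphabet
#' @return a single WindowSet
#' @export
bindWindows <- function(sets) {
  stopifnot(length(sets) >= 1L)
  w <- sets[[1L]]@width
  for (s in sets) stopifnot(s@width == w,
                            identical(s@alphabet@states, sets[[1L]]@alphabet@states))
  new("WindowSet",
      profiles = do.call(rbind, lapply(sets, function(s) s@profiles)),
      width = w, alphabet = sets[[1L]]@alphabet,
      info = do.call(rbind, lapply(sets, function(s) s@info)))
}

#' Subset a window set
#' @param x WindowSet
#' @param i row indices
#' @export
subsetWindows <- function(x, i) {
  new("WindowSet", profiles = x@profiles[i, , drop = FALSE], width = x@width,
      alphabet = x@alphabet, info = x@info[i, , drop = FALSE])
}

setMethod("show", "WindowSet", function(object) {
  cat(sprintf("WindowSet: %d windows, width %d, alphabet '%s' (%d states)\n",
              nrow(object@profiles), object@width, object@alphabet@name,
              nStates(object@alphabet)))
  if ("class" %in% names(object@info)) {
    tb <- table(object@info$class, useNA = "ifany")
    cat("  classes:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
})

#' Difficulty-balanced fold assignment
#'
#' Benchmarks are grouped by difficulty bin and dealt round-robin (after a
#' seeded shuffle within each bin) across folds, so every fold sees a
#' balanced mix of difficulties.
#'
#' @param difficulty per-benchmark difficulty (accuracy of the default
#'   alignment)
#' @param nFolds number of cross-validation folds
#' @param seed RNG seed
#' @return integer fold assignment per benchmark (1..nFolds)
#' @export
assignFolds <- function(difficulty, nFolds = 12L, seed = 1L) {
  bins <- difficultyBin(difficulty)
  folds <- integer(length(difficulty))
  .withSeed(seed, {
    nxt <- 0L
    for (b in sort(unique(bins))) {
      members <- which(bins == b)
      members <- members[sample.int(length(members))]
      folds[members] <- (nxt + seq_along(members) - 1L) %% nFolds + 1L
      nxt <- nxt + length(members)
    }
  })
  folds
}

#' Assemble training and testing window sets
#'
#' From a labeled window pool with a per-window fold assignment, draw for
#' each structured class a full training set Tc and a training sample
#' Sc from the non-test folds, a subsample of the unstructured (all
#' non-core) class for bottom-impostor constraints, and a held-out test set
#' from the test folds (all classes, excluded patterns included: prediction
#' never sees labels).
#'
#' @param pool a labeled \linkS4class{WindowSet}
#' @param fold integer fold id per window
#' @param testFolds fold ids reserved for testing
#' @param sizeT per-class full training-set size
#' @param sizeS total training-sample size (split evenly across the five
#'   structured classes)
#' @param sizeTest held-out test-set size
#' @param sizeBottom subsample size of unstructured training windows
#' @param seed RNG seed (sampling is uniform without replacement)
#' @return a \linkS4class{WindowSets}
#' @export
assembleWindowSets <- function(pool, fold, testFolds, sizeT, sizeS,
                               sizeTest, sizeBottom = sizeT, seed = 1L) {
  stopifnot(length(fold) == nrow(pool@profiles))
  isTest <- fold %in% testFolds
  cls <- pool@info$class
  take <- function(avail, size, what) {
    if (length(avail) < size)
      stop("requested ", size, " ", what, " windows but only ",
           length(avail), " available")
    avail[sample.int(length(avail), size)]
  }
  perClassS <- rep(sizeS %/% 5L, 5L)
  extra <- sizeS - sum(perClassS)
  if (extra > 0L) perClassS[seq_len(extra)] <- perClassS[seq_len(extra)] + 1L
  names(perClassS) <- .STRUCTURED_CLASSES
  Tc <- list(); Sc <- list(); bottom <- integer(); test <- integer()
  .withSeed(seed, {
    for (cl in .STRUCTURED_CLASSES) {
      avail <- which(!isTest & !is.na(cls) & cls == cl)
      Tc[[cl]] <- sort(take(avail, sizeT, cl))
      Sc[[cl]] <- sort(Tc[[cl]][sample.int(sizeT, perClassS[[cl]])])
    }
    availB <- which(!isTest & !is.na(cls) & cls == "NNN")
    bottom <- sort(take(availB, sizeBottom, "unstructured"))
    availT <- which(isTest)
    test <- sort(take(availT, sizeTest, "test"))
  })
  new("WindowSets", pool = pool, Tc = Tc, Sc = Sc, bottom = bottom,
      test = test, trainPool = which(!isTest), seed = as.integer(seed),
      sizes = list(T = sizeT, S = sizeS, test = sizeTest,
                   bottom = sizeBottom))
}

setMethod("show", "WindowSets", function(object) {
  cat("WindowSets over a pool of", nrow(object@pool@profiles), "windows\n")
  cat("  |Tc| =", paste(vapply(object@Tc, length, 1L), collapse = "/"),
      " |Sc| =", paste(vapply(object@Sc, length, 1L), collapse = "/"),
      " bottom =", length(object@bottom),
      " test =", length(object@test), "\n")
})
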