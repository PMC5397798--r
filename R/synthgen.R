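#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the structure of protein reference-alignment
#' benchmarks: core columns are gap-free and drawn from a low-entropy
#' residue distribution inside helix/strand secondary-structure runs;
#' non-core columns are gappy, near-uniform in residue, and coil.
#' Alternate "computed" alignments of controlled true accuracy are derived
#' from the reference by displacing core residues.
#'
#' @param nBenchmarks number of benchmarks in a suite
#' @param k sequences per benchmark
#' @param m reference columns per benchmark
#' @param coreFraction fraction of columns that are core
#' @param coreConservation probability a core residue equals its column's
#'   consensus
#' @param nonCoreGapRate per-cell gap probability in non-core columns
#' @param runMean mean run length of core/non-core segments (runs are at
#'   least 2 columns, so excluded window patterns are rare)
#' @param sharpness Dirichlet concentration on the true secondary-structure
#'   state (10 = peaked but not one-hot, PSIPRED-like)
#' @param accuracyLevels explicit target accuracies for every benchmark's
#'   computed alignments, or NULL (the default) to emulate a
#'   parameter-advising universe: each benchmark gets a difficulty (the
#'   default setting's accuracy, spread evenly over benchmarks so all
#'   difficulty bins are populated) and \code{nCandidates - 1} alternate
#'   settings whose accuracies jitter around it by up to
#'   \code{candidateSpread} -- so which setting wins varies by benchmark,
#'   as with a real aligner's parameter choices
#' @param nCandidates computed alignments per benchmark (first = default)
#' @param candidateSpread half-width of the alternate-setting accuracy
#'   jitter
#' @param seed RNG seed (mandatory; every draw is reproducible)
#' @return a list of class \code{"SuiteConfig"}
#' @export
suiteConfig <- function(nBenchmarks = 12L, k = 8L, m = 60L,
                        coreFraction = 0.5, coreConservation = 0.9,
                        nonCoreGapRate = 0.4, runMean = 6,
                        sharpness = 10,
                        accuracyLevels = NULL, nCandidates = 10L,
                        candidateSpread = 0.2,
                        seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(coreFraction > 0, coreFraction <= 1,
            coreConservation >= 0, coreConservation <= 1,
            nonCoreGapRate >= 0, nonCoreGapRate <= 1,
            is.null(accuracyLevels) ||
              all(accuracyLevels >= 0 & accuracyLevels <= 1),
            nCandidates >= 1L, candidateSpread >= 0, candidateSpread <= 1)
  structure(list(nBenchmarks = as.integer(nBenchmarks), k = as.integer(k),
                 m = as.integer(m), coreFraction = coreFraction,
                 coreConservation = coreConservation,
                 nonCoreGapRate = nonCoreGapRate, runMean = runMean,
                 sharpness = sharpness, accuracyLevels = accuracyLevels,
                 nCandidates = as.integer(nCandidates),
                 candidateSpread = candidateSpread,
                 seed = as.integer(seed)),
            class = "SuiteConfig")
}

# accuracy targets of one benchmark's computed alignments
.benchmarkLevels <- function(config, difficulty, seed) {
  if (!is.null(config$accuracyLevels)) return(config$accuracyLevels)
  .withSeed(seed, {
    alt <- difficulty + stats::runif(config$nCandidates - 1L,
                                     -config$candidateSpread,
                                     config$candidateSpread)
    c(difficulty, pmin(pmax(alt, 0.02), 1))
  })
}

# alternating core/non-core run labels totaling m columns, core share about
# coreFraction, every run at least 2 columns
.coreLabelRuns <- function(m, coreFraction, runMean) {
  labels <- character(0)
  core <- stats::runif(1) < coreFraction
  nCore <- round(m * coreFraction)
  while (length(labels) < m) {
    len <- 2L + stats::rpois(1L, max(runMean - 2, 0.1))
    want <- if (core) nCore - sum(labels == "C") else
      (m - nCore) - sum(labels == "N")
    len <- min(len, max(want, 0L), m - length(labels))
    if (len > 0L)
      labels <- c(labels, rep(if (core) "C" else "N", len))
    core <- !core
    # both quotas filled: pad with whichever side remains
    if (sum(labels == "C") >= nCore && length(labels) < m &&
        sum(labels == "N") >= m - nCore) break
  }
  if (length(labels) < m)
    labels <- c(labels, rep(if (sum(labels == "C") < nCore) "C" else "N",
                            m - length(labels)))
  labels[seq_len(m)]
}

.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), alpha)
  x / sum(x)
}

#' Generate a synthetic reference alignment
#'
#' Core columns are gap-free with a consensus residue each sequence copies
#' with probability \code{coreConservation}; non-core columns carry gaps at
#' the configured rate and uniform residues. Secondary structure follows
#' the core segments (each core run is a helix or strand, non-core is
#' coil), and per-residue confidences are Dirichlet draws peaked on the
#' true state.
#'
#' @param config a \code{\link{suiteConfig}}
#' @param seed RNG seed for this benchmark
#' @return list with \code{reference} (ProteinAlignment),
#'   \code{annotation} (0/1 per column), \code{ss} (confidence matrices)
#' @export
generateReference <- function(config, seed) {
  k <- config$k; m <- config$m
  out <- .withSeed(seed, {
    labels <- .coreLabelRuns(m, config$coreFraction, config$runMean)
    if (!any(labels == "C"))
      stop("core fraction too small: no core columns generated")
    # secondary structure per column: core runs alternate helix/strand
    ssCol <- rep("C", m)
    runs <- rle(labels)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    coreRun <- 0L
    for (t in seq_along(runs$lengths)) {
      if (runs$values[t] == "C") {
        coreRun <- coreRun + 1L
        ssCol[starts[t]:ends[t]] <- if (coreRun %% 2L) "H" else "E"
      }
    }
    seqs <- matrix(.GAP, k, m)
    for (j in seq_len(m)) {
      if (labels[j] == "C") {
        consensus <- sample(.AA20, 1L)
        pick <- stats::runif(k) < config$coreConservation
        seqs[, j] <- ifelse(pick, consensus, sample(.AA20, k, replace = TRUE))
      } else {
        gap <- stats::runif(k) < config$nonCoreGapRate
        seqs[, j] <- ifelse(gap, .GAP, sample(.AA20, k, replace = TRUE))
      }
    }
    # avoid fully empty rows/columns in pathological draws
    for (s in seq_len(k)) if (all(seqs[s, ] == .GAP))
      seqs[s, sample.int(m, 1L)] <- sample(.AA20, 1L)
    rownames(seqs) <- sprintf("seq%02d", seq_len(k))
    aln <- new("ProteinAlignment", seqs = seqs, ambiguous = FALSE)
    ssIdx <- match(ssCol, .SS3)
    ss <- lapply(seq_len(k), function(s) {
      cols <- which(seqs[s, ] != .GAP)
      conf <- t(vapply(cols, function(j) {
        a <- rep(1, 3); a[ssIdx[j]] <- config$sharpness
        .rdirichlet1(a)
      }, numeric(3)))
      colnames(conf) <- .SS3
      attr(conf, "residues") <- seqs[s, cols]
      conf
    })
    names(ss) <- rownames(seqs)
    list(reference = aln, annotation = as.numeric(labels == "C"), ss = ss)
  })
  out
}

#' Derive a computed alignment of controlled true accuracy
#'
#' Misalignment is emulated the way aligners actually err, by two
#' mechanisms with exact core-pair accounting:
#' \itemize{
#'   \item \emph{Block shifts}: a subset of g sequences slides one column
#'     to the right across a short column window, so its residues land in
#'     columns holding the other sequences' residues from the next
#'     reference column. Each core column t in the window loses the
#'     a_t * b_t pairs between the shifted and unshifted groups while both
#'     groups keep their internal pairs; the affected columns become mixed
#'     columns of fractional coreness and the column count grows by at
#'     most one per shift.
#'   \item \emph{Fraying}: single residues (occasionally small blocks,
#'     piece sizes sampled with geometrically decaying weights) slip out of
#'     core columns, merging into an adjacent gap column or into a fresh
#'     inserted column, for fine-grained control near the target.
#' }
#' Shifted and frayed column ranges stay disjoint, no two residues of the
#' same reference core column are ever re-aligned, and residue order is
#' preserved, so the realized preserved-core-pair fraction is exact; the
#' procedure stops as close to the target as the pair granularity allows
#' (error if not within 0.05).
#'
#' @param reference ProteinAlignment
#' @param annotation 0/1 core annotation of the reference
#' @param accuracy target true accuracy in [0, 1]
#' @param seed RNG seed
#' @param mixRate probability a frayed singleton merges into an adjacent
#'   column rather than a fresh one
#' @return list: \code{alignment} (ProteinAlignment) and
#'   \code{realized} (the realized preserved-core-pair fraction)
#' @export
generateComputed <- function(reference, annotation, accuracy, seed,
                             mixRate = 0.5) {
  stopifnot(accuracy >= 0, accuracy <= 1)
  seqs <- msaMatrix(reference)
  k <- nrow(seqs); m <- ncol(seqs)
  isCore <- annotation == 1
  nIn <- vapply(seq_len(m), function(j) sum(seqs[, j] != .GAP), integer(1))
  totalPairs <- sum(.choose2(nIn[isCore]))
  if (accuracy < 1 && totalPairs == 0L)
    stop("target accuracy below 1 is unreachable: reference has no core pairs")
  target <- accuracy * totalPairs
  plan <- .withSeed(seed, {
    used <- rep(FALSE, m)
    preserved <- totalPairs
    locked <- 0       # pairs pinned inside shifted/grouped blocks
    shifts <- list()  # list(members, j1, j2)
    frays <- list()   # c(column, piece size)
    intact <- stats::setNames(nIn, seq_len(m))
    gw <- function(n) 3^(-(seq_len(n) - 1L))   # small-piece bias
    # phase 1: block shifts over unused column windows
    misses <- 0L
    while (preserved - target > 1e-9 && misses < 300L && m >= 3L) {
      need <- preserved - target
      L <- 1L + stats::rpois(1L, 1.0)
      j1 <- sample.int(m - L, 1L)
      j2 <- j1 + L - 1L
      if (any(used[j1:j2])) { misses <- misses + 1L; next }
      # draw a sequence ordering and shrink the shifted subset until the
      # move fits the remaining need (never overshoot: fraying can only
      # reduce further, so the target is approached from above)
      perm <- sample.int(k)
      cols <- j1:j2
      coreT <- isCore[cols]
      G <- NULL; delta <- 0; floorAdd <- 0
      for (g in rev(seq_len(k - 1L))) {
        Gg <- perm[seq_len(g)]
        aT <- vapply(cols, function(t) sum(seqs[Gg, t] != .GAP), integer(1))
        bT <- vapply(cols, function(t) nIn[t], integer(1)) - aT
        dg <- sum((aT * bT)[coreT])
        fg <- sum((.choose2(aT) + .choose2(bT))[coreT])
        if (dg > 0 && dg <= need && locked + fg <= target) {
          G <- Gg; delta <- dg; floorAdd <- fg
          break
        }
      }
      if (is.null(G)) { misses <- misses + 1L; next }
      # the spill (G's residues from the last window column) merges into
      # the following column when that column is non-core and a gap for
      # every spilled member -- a mixed column of fractional coreness, the
      # way a real shift runs into gap space; otherwise it gets a fresh
      # column of its own
      spillMembers <- G[seqs[G, j2] != .GAP]
      mergeSpill <- length(spillMembers) > 0L && j2 + 1L <= m &&
        !used[j2 + 1L] && !isCore[j2 + 1L] &&
        all(seqs[spillMembers, j2 + 1L] == .GAP)
      used[j1:j2] <- TRUE
      if (mergeSpill) used[j2 + 1L] <- TRUE
      preserved <- preserved - delta
      locked <- locked + floorAdd
      shifts[[length(shifts) + 1L]] <- list(members = G, j1 = j1, j2 = j2,
                                            mergeSpill = mergeSpill)
      misses <- 0L
    }
    # phase 2: fraying on untouched core columns
    repeat {
      need <- preserved - target
      cand <- which(isCore & !used & intact >= 2L)
      if (!length(cand) || need <= 1e-9) break
      ops <- list(); wts <- numeric(0)
      for (j in cand) {
        cc <- intact[[j]]
        for (g in seq_len(cc - 1L)) {
          delta <- g * (cc - g)
          if (delta > need) next
          if (g >= 2L && locked + .choose2(g) > target) next
          ops[[length(ops) + 1L]] <- c(j, g, delta)
          wts <- c(wts, 3^(-(g - 1L)))
        }
      }
      if (!length(ops)) break
      pick <- ops[[sample.int(length(ops), 1L, prob = wts)]]
      frays[[length(frays) + 1L]] <- pick[1:2]
      intact[[pick[1L]]] <- intact[[pick[1L]]] - pick[2L]
      preserved <- preserved - pick[3L]
      if (pick[2L] >= 2L) locked <- locked + .choose2(pick[2L])
    }
    list(shifts = shifts, frays = frays, used = used,
         realized = preserved / max(totalPairs, 1L))
  })
  if (totalPairs > 0L && abs(plan$realized - accuracy) > 0.05)
    stop(sprintf("could not reach target accuracy %.3f (closest %.3f)",
                 accuracy, plan$realized))
  ## ---- assembly ----------------------------------------------------------
  current <- seqs
  extras <- lapply(seq_len(m), function(j) list())  # columns inserted after j
  # block shifts: G's residues move one column right inside [j1, j2]; the
  # last one spills into a fresh column after j2
  for (sh in plan$shifts) {
    G <- sh$members; j1 <- sh$j1; j2 <- sh$j2
    keepG <- G[seqs[G, j2] != .GAP]
    if (length(keepG)) {
      if (isTRUE(sh$mergeSpill)) {
        current[keepG, j2 + 1L] <- seqs[keepG, j2]
      } else {
        extras[[j2]] <- c(extras[[j2]],
                          list(stats::setNames(seqs[keepG, j2], keepG)))
      }
    }
    if (j2 > j1)
      current[G, (j1 + 1L):j2] <- seqs[G, j1:(j2 - 1L), drop = FALSE]
    current[G, j1] <- .GAP
  }
  # fraying: pick members at placement time so singletons can merge into
  # adjacent original-gap columns (never into shift-affected ones)
  avail <- stats::setNames(lapply(seq_len(m), function(j)
    which(seqs[, j] != .GAP)), seq_len(m))
  placedFrom <- lapply(seq_len(m), function(j) integer(0))
  current <- .withSeed(seed + 1L, {
    for (fr in plan$frays) {
      j <- fr[1L]; g <- fr[2L]
      jk <- as.character(j)
      merged <- FALSE
      if (stats::runif(1) < mixRate) {
        adjs <- c(j - 1L, j + 1L)
        adjs <- adjs[adjs >= 1L & adjs <= m]
        adjs <- adjs[!plan$used[adjs]]
        adjs <- adjs[sample.int(length(adjs))]
        for (a in adjs) {
          if (j %in% placedFrom[[a]]) next
          elig <- avail[[jk]][seqs[avail[[jk]], a] == .GAP &
                              current[avail[[jk]], a] == .GAP]
          if (length(elig) < g) next
          members <- elig[sample.int(length(elig), g)]
          current[members, a] <- seqs[members, j]
          current[members, j] <- .GAP
          placedFrom[[a]] <- c(placedFrom[[a]], j)
          avail[[jk]] <- setdiff(avail[[jk]], members)
          merged <- TRUE
          break
        }
      }
      if (merged) next
      members <- avail[[jk]][sample.int(length(avail[[jk]]), g)]
      avail[[jk]] <- setdiff(avail[[jk]], members)
      current[members, j] <- .GAP
      extras[[j]] <- c(extras[[j]],
                       list(stats::setNames(seqs[members, j], members)))
    }
    # occasionally pull a foreign residue of the following untouched
    # non-core column into the last fresh column of a frayed source
    for (fr in plan$frays) {
      j <- fr[1L]
      a <- j + 1L
      t <- length(extras[[j]])
      if (t == 0L || a > m || annotation[a] != 0 || plan$used[a]) next
      if (stats::runif(1) >= mixRate) next
      col <- extras[[j]][[t]]
      outOfJ <- setdiff(which(seqs[, j] != .GAP), avail[[as.character(j)]])
      ok <- which(current[, a] != .GAP & seqs[, a] != .GAP)
      ok <- setdiff(ok, c(outOfJ, as.integer(names(col))))
      if (!length(ok)) next
      s <- ok[sample.int(length(ok), 1L)]
      col[as.character(s)] <- current[s, a]
      current[s, a] <- .GAP
      extras[[j]][[t]] <- col
    }
    current
  })
  colsOut <- vector("list", m)
  for (j in seq_len(m)) {
    extra <- NULL
    if (length(extras[[j]])) {
      extra <- matrix(.GAP, k, length(extras[[j]]))
      for (t in seq_along(extras[[j]])) {
        col <- extras[[j]][[t]]
        extra[as.integer(names(col)), t] <- col
      }
    }
    colsOut[[j]] <- cbind(matrix(current[, j], k, 1L), extra)
  }
  newSeqs <- do.call(cbind, colsOut)
  keep <- colSums(newSeqs != .GAP) > 0L
  newSeqs <- newSeqs[, keep, drop = FALSE]
  rownames(newSeqs) <- rownames(seqs)
  list(alignment = new("ProteinAlignment", seqs = newSeqs,
                       ambiguous = FALSE),
       realized = if (totalPairs > 0L) plan$realized else 1)
}

#' Generate one benchmark in memory
#'
#' A reference with core annotation and secondary structure plus one
#' computed alignment per accuracy level (see \code{\link{suiteConfig}}:
#' either the explicit levels, or a default-setting accuracy equal to
#' \code{difficulty} plus jittered alternates).
#'
#' @param config a \code{\link{suiteConfig}}
#' @param seed RNG seed for this benchmark
#' @param difficulty default-setting accuracy when levels are not explicit
#' @return a benchmark list (same shape as \code{\link{loadBenchmark}})
#' @export
generateBenchmark <- function(config, seed, difficulty = 0.5) {
  ref <- generateReference(config, seed)
  levels <- .benchmarkLevels(config, difficulty, seed + 1L)
  computed <- list(); acc <- numeric(0)
  for (t in seq_along(levels)) {
    gc <- generateComputed(ref$reference, ref$annotation, levels[t],
                           seed = seed + 7919L * t)
    id <- sprintf("p%02d", t)
    computed[[id]] <- gc$alignment
    acc[id] <- gc$realized
  }
  list(reference = ref$reference, annotation = ref$annotation, ss = ref$ss,
       computed = computed, accuracy = acc)
}

# benchmark difficulties covering all difficulty bins but weighted toward
# easy benchmarks, as in curated protein benchmark collections (quantiles
# of a Beta(2.5, 1) distribution)
.suiteDifficulties <- function(n) {
  if (n == 1L) return(0.5)
  stats::qbeta((seq_len(n) - 0.5) / n, 2.5, 1)
}

#' Generate a benchmark suite on disk
#'
#' Writes, per benchmark, the reference FASTA, core-annotation TSV, one
#' .ss2 file per sequence, one aligned FASTA per accuracy level, and a
#' manifest JSON tying them together (with realized accuracies recorded).
#'
#' @param config a \code{\link{suiteConfig}}
#' @param dir output directory (created)
#' @return character vector of manifest paths
#' @export
generateSuite <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  diffs <- .suiteDifficulties(config$nBenchmarks)
  manifests <- character(config$nBenchmarks)
  for (bi in seq_len(config$nBenchmarks)) {
    bdir <- file.path(dir, sprintf("bench%03d", bi))
    dir.create(bdir, showWarnings = FALSE)
    bm <- generateBenchmark(config, seed = config$seed + 104729L * bi,
                            difficulty = diffs[bi])
    writeAlignment(bm$reference, file.path(bdir, "reference.fasta"))
    writeCoreAnnotation(bm$annotation, file.path(bdir, "core.tsv"))
    ssPaths <- list()
    for (id in msaIDs(bm$reference)) {
      p <- file.path(bdir, paste0(id, ".ss2"))
      writeSS2(bm$ss[[id]], p)
      ssPaths[[id]] <- basename(p)
    }
    computed <- list()
    for (id in names(bm$computed)) {
      p <- file.path(bdir, paste0(id, ".fasta"))
      writeAlignment(bm$computed[[id]], p)
      computed[[length(computed) + 1L]] <-
        list(id = id, path = basename(p), accuracy = bm$accuracy[[id]])
    }
    manifest <- list(reference = "reference.fasta",
                     core_annotation = "core.tsv",
                     ss2 = ssPaths, computed = computed)
    manifests[bi] <- file.path(bdir, "manifest.json")
    writeManifest(manifest, manifests[bi])
  }
  manifests
}
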