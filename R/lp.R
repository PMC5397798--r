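# Layout of the unordered state-pair variables of one (class, position)
# score table: pairs (p <= q) excluding (gap, gap), whose score is fixed at
# zero and carries no variable.
.pairLayout <- function(ns) {
  ut <- which(upper.tri(matrix(0, ns, ns), diag = TRUE), arr.ind = TRUE)
  keep <- !(ut[, 1L] == ns & ut[, 2L] == ns)
  pu <- ut[keep, 1L]; qu <- ut[keep, 2L]
  idx <- matrix(NA_integer_, ns, ns)
  idx[cbind(pu, qu)] <- seq_along(pu)
  idx[cbind(qu, pu)] <- seq_along(pu)
  list(pu = pu, qu = qu, idx = idx, n = length(pu))
}

# Coefficients of d(V, W) on the unordered-pair variables, batched over rows
# of Wm/Vm: row r, position block i holds V_i(p)W_i(q) + V_i(q)W_i(p) for
# p < q and V_i(p)W_i(p) on the diagonal pairs.
.pairCoef <- function(Wm, Vm, ns, P, lay) {
  np <- lay$n
  out <- matrix(0, nrow(Wm), P * np)
  dg <- lay$pu == lay$qu
  for (i in seq_len(P)) {
    Wi <- .posBlock(Wm, i, ns)
    Vi <- .posBlock(Vm, i, ns)
    C <- Wi[, lay$pu, drop = FALSE] * Vi[, lay$qu, drop = FALSE] +
         Wi[, lay$qu, drop = FALSE] * Vi[, lay$pu, drop = FALSE]
    C[, dg] <- C[, dg] / 2
    out[, (i - 1L) * np + seq_len(np)] <- C
  }
  out
}

#' Targets and impostors for the distance-learning LP
#'
#' For every window W in the per-class training samples: k target windows of
#' W's own class and l impostor windows from each other structured class;
#' plus, for a subsample of unstructured (all non-core) windows, l impostors
#' from each core class. Neighborhoods are found by nearest-neighbor search
#' under the default distance (\code{mode = "default"}), under a previously
#' learned model (\code{mode = "model"}), or by seeded uniform sampling
#' without replacement (\code{mode = "random"}).
#'
#' @param sets a \linkS4class{WindowSets}
#' @param mode "random", "default" or "model"
#' @param k targets per sample window
#' @param l impostors per sample window per class
#' @param seed RNG seed (used by mode "random")
#' @param model DistanceModel for mode "model"
#' @param gammaMix mixing weight of the default distance
#' @return a list of class \code{"Neighborhoods"}
#' @export
buildNeighborhoods <- function(sets, mode = c("random", "default", "model"),
                               k = 2L, l = 150L, seed = 1L, model = NULL,
                               gammaMix = 0.5) {
  mode <- match.arg(mode)
  stopifnot(k >= 1L, l >= 1L)
  pool <- sets@pool
  for (cl in .STRUCTURED_CLASSES) {
    if (length(sets@Tc[[cl]]) < k + 1L)
      stop("class ", cl, " has ", length(sets@Tc[[cl]]),
           " training windows; need at least k+1 = ", k + 1L)
    if (length(sets@Tc[[cl]]) < l)
      stop("class ", cl, " has fewer than l = ", l, " training windows")
  }
  if (mode == "default")
    model <- defaultDistanceModel(pool@alphabet, pool@width, gammaMix)
  if (mode == "model" && is.null(model))
    stop("mode 'model' requires a DistanceModel")
  prof <- pool@profiles
  targets <- list(); impostors <- list()
  nnPick <- function(D, n, excludeCol = NULL) {
    # n smallest per row, ties by column (insertion) order
    t(vapply(seq_len(nrow(D)), function(r) {
      d <- D[r, ]
      if (!is.null(excludeCol) && !is.na(excludeCol[r])) d[excludeCol[r]] <- Inf
      order(d, seq_along(d))[seq_len(n)]
    }, integer(n)))
  }
  .withSeed(seed, {
    for (cl in .STRUCTURED_CLASSES) {
      S <- sets@Sc[[cl]]; Tc <- sets@Tc[[cl]]
      if (mode == "random") {
        tg <- t(vapply(S, function(wIdx) {
          cand <- setdiff(Tc, wIdx)
          cand[sample.int(length(cand), k)]
        }, integer(k)))
      } else {
        D <- windowCrossDist(model, cl, prof[S, , drop = FALSE],
                             prof[Tc, , drop = FALSE])
        tg <- matrix(Tc[nnPick(D, k, excludeCol = match(S, Tc))],
                     nrow = length(S))
      }
      targets[[cl]] <- matrix(tg, nrow = length(S), ncol = k)
      impostors[[cl]] <- list()
      for (bl in setdiff(.STRUCTURED_CLASSES, cl)) {
        Tb <- sets@Tc[[bl]]
        if (mode == "random") {
          im <- t(vapply(S, function(wIdx)
            Tb[sample.int(length(Tb), l)], integer(l)))
        } else {
          D <- windowCrossDist(model, bl, prof[S, , drop = FALSE],
                               prof[Tb, , drop = FALSE])
          im <- matrix(Tb[nnPick(D, l)], nrow = length(S))
        }
        impostors[[cl]][[bl]] <- matrix(im, nrow = length(S), ncol = l)
      }
    }
    bottomImp <- list()
    for (bl in .CORE_CLASSES) {
      Tb <- sets@Tc[[bl]]
      if (mode == "random") {
        im <- t(vapply(sets@bottom, function(wIdx)
          Tb[sample.int(length(Tb), l)], integer(l)))
      } else {
        D <- windowCrossDist(model, bl, prof[sets@bottom, , drop = FALSE],
                             prof[Tb, , drop = FALSE])
        im <- matrix(Tb[nnPick(D, l)], nrow = length(sets@bottom))
      }
      bottomImp[[bl]] <- matrix(im, nrow = length(sets@bottom), ncol = l)
    }
  })
  structure(list(mode = mode, k = as.integer(k), l = as.integer(l),
                 seed = as.integer(seed), samples = sets@Sc,
                 targets = targets, impostors = impostors,
                 bottomSamples = sets@bottom, bottomImpostors = bottomImp),
            class = "Neighborhoods")
}

#' Build the distance-learning linear program
#'
#' Variables: one substitution score per (structured class, window position,
#' unordered state pair) — symmetry is imposed structurally and the
#' (gap, gap) score is fixed at zero — plus a target error variable per
#' (sample window, target), one impostor error variable per sample window,
#' and the threshold tau. Constraints: target rows
#' e >= d_c(V,W) - tau, impostor rows f >= tau - d_b(V,W) + 1 (margin 1,
#' including unstructured-vs-core rows), self-dissimilarity rows
#' sigma(p,p) <= sigma(p,q), and (optionally deferred) triangle rows
#' sigma(p,r) <= sigma(p,q) + sigma(q,r) for all state triples. The
#' objective is alpha times the mean target error (averaged per class, per
#' window, per target) plus (1 - alpha) times the mean impostor error
#' (averaged over the six classes, the unstructured sample included).
#'
#' @param sets a \linkS4class{WindowSets}
#' @param nbhd Neighborhoods from \code{\link{buildNeighborhoods}}
#' @param alpha blend weight on target error, in [0, 1]
#' @param triangles "full" enumerates all triangle rows; "none" defers them
#'   (for lazy generation in \code{\link{solveDistanceLP}})
#' @param impostors "all" emits every impostor row up front; "lazy" defers
#'   them to cutting-plane generation in \code{\link{solveDistanceLP}}
#'   (for each impostor error variable only the minimum-distance impostor
#'   can bind, so few rows are ever active)
#' @return an LP description (class \code{"coreLP"})
#' @export
buildDistanceLP <- function(sets, nbhd, alpha = 0.5,
                            triangles = c("full", "none"),
                            impostors = c("all", "lazy")) {
  triangles <- match.arg(triangles)
  impostors <- match.arg(impostors)
  stopifnot(alpha >= 0, alpha <= 1)
  pool <- sets@pool
  ns <- nStates(pool@alphabet)
  P <- 2L * pool@width + 1L
  lay <- .pairLayout(ns)
  np <- lay$n
  nC <- length(.STRUCTURED_CLASSES)
  nSigma <- nC * P * np
  sigOff <- function(ci) (ci - 1L) * P * np

  nE <- sum(vapply(nbhd$samples, length, 1L)) * nbhd$k
  nF <- sum(vapply(nbhd$samples, length, 1L)) + length(nbhd$bottomSamples)
  tauIdx <- nSigma + nE + nF + 1L
  nCols <- tauIdx

  ti <- list(); tj <- list(); tv <- list(); rhs <- list()
  nRows <- 0L
  addRows <- function(i, j, v, b) {
    keep <- v != 0
    ti[[length(ti) + 1L]] <<- i[keep] + nRows
    tj[[length(tj) + 1L]] <<- j[keep]
    tv[[length(tv) + 1L]] <<- v[keep]
    rhs[[length(rhs) + 1L]] <<- b
    nRows <<- nRows + length(b)
  }

  prof <- pool@profiles
  eMap <- list(); fMap <- list()
  eAt <- nSigma; fAt <- nSigma + nE
  # impostor error variable of every sample window, assigned up front
  for (ci in seq_len(nC)) {
    cl <- .STRUCTURED_CLASSES[ci]
    n <- length(nbhd$samples[[cl]])
    fMap[[cl]] <- data.frame(class = cl, W = nbhd$samples[[cl]],
                             var = fAt + seq_len(n))
    fAt <- fAt + n
  }
  fMap[["NNN"]] <- data.frame(class = "NNN", W = nbhd$bottomSamples,
                              var = fAt + seq_along(nbhd$bottomSamples))

  # target constraints: d_c(V, W) - tau - e <= 0
  for (ci in seq_len(nC)) {
    cl <- .STRUCTURED_CLASSES[ci]
    S <- nbhd$samples[[cl]]
    n <- length(S)
    for (t in seq_len(nbhd$k)) {
      Vidx <- nbhd$targets[[cl]][, t]
      coef <- .pairCoef(prof[S, , drop = FALSE], prof[Vidx, , drop = FALSE],
                        ns, P, lay)
      eVars <- eAt + seq_len(n)
      eAt <- eAt + n
      eMap[[length(eMap) + 1L]] <- data.frame(class = cl, W = S, V = Vidx,
                                              var = eVars)
      rows <- rep(seq_len(n), P * np + 2L)
      cols <- c(rep(sigOff(ci) + seq_len(P * np), each = n),
                rep(tauIdx, n), eVars)
      vals <- c(as.vector(coef), rep(-1, n), rep(-1, n))
      addRows(rows, cols, vals, rep(0, n))
    }
  }
  eMap <- do.call(rbind, eMap)

  # impostor constraints: tau - d_b(V, W) - f <= -1
  impRows <- list()
  addImpostors <- function(Widx, impMat, bClass, fVars) {
    bi <- match(bClass, .STRUCTURED_CLASSES)
    n <- length(Widx)
    for (t in seq_len(ncol(impMat))) {
      Vidx <- impMat[, t]
      if (impostors == "all") {
        coef <- .pairCoef(prof[Widx, , drop = FALSE],
                          prof[Vidx, , drop = FALSE], ns, P, lay)
        rows <- rep(seq_len(n), P * np + 2L)
        cols <- c(rep(sigOff(bi) + seq_len(P * np), each = n),
                  rep(tauIdx, n), fVars)
        vals <- c(-as.vector(coef), rep(1, n), rep(-1, n))
        addRows(rows, cols, vals, rep(-1, n))
      }
      impRows[[length(impRows) + 1L]] <<- data.frame(
        W = Widx, V = Vidx, bClass = bClass, fVar = fVars)
    }
  }
  for (cl in .STRUCTURED_CLASSES) {
    S <- nbhd$samples[[cl]]
    fVars <- fMap[[cl]]$var
    for (bl in setdiff(.STRUCTURED_CLASSES, cl))
      addImpostors(S, nbhd$impostors[[cl]][[bl]], bl, fVars)
  }
  for (bl in .CORE_CLASSES)
    addImpostors(nbhd$bottomSamples, nbhd$bottomImpostors[[bl]], bl,
                 fMap[["NNN"]]$var)
  impMapAll <- do.call(rbind, impRows)

  # self rows: sigma(p,p) - sigma(p,q) <= 0 (p non-gap, q != p)
  for (ci in seq_len(nC)) {
    for (i in seq_len(P)) {
      off <- sigOff(ci) + (i - 1L) * np
      pp <- rep(seq_len(ns - 1L), each = ns - 1L)
      qq <- as.vector(vapply(seq_len(ns - 1L),
                             function(p) setdiff(seq_len(ns), p),
                             integer(ns - 1L)))
      n <- length(pp)
      rows <- rep(seq_len(n), 2L)
      cols <- c(off + lay$idx[cbind(pp, pp)], off + lay$idx[cbind(pp, qq)])
      addRows(rows, cols, c(rep(1, n), rep(-1, n)), rep(0, n))
    }
  }

  if (triangles == "full") {
    tri <- .triangleTriples(ns)
    for (ci in seq_len(nC)) for (i in seq_len(P))
      addRows(tri$rows, sigOff(ci) + (i - 1L) * np + tri$cols, tri$vals,
              rep(0, nrow(tri$triples)))
  }

  obj <- numeric(nCols)
  sizesS <- vapply(nbhd$samples, length, 1L)
  for (r in seq_len(nrow(eMap))) {
    cl <- eMap$class[r]
    obj[eMap$var[r]] <- alpha / (nC * sizesS[[cl]] * nbhd$k)
  }
  nClassesAll <- nC + 1L   # the six classes, unstructured included
  for (cl in names(fMap)) {
    n <- nrow(fMap[[cl]])
    if (n) obj[fMap[[cl]]$var] <- (1 - alpha) / (nClassesAll * n)
  }

  structure(list(i = unlist(ti), j = unlist(tj), v = unlist(tv),
                 b = unlist(rhs), obj = obj, nRows = nRows, nCols = nCols,
                 meta = list(ns = ns, P = P, lay = lay, nSigma = nSigma,
                             tauIdx = tauIdx, eMap = eMap,
                             impMap = impMapAll, fMap = fMap,
                             alpha = alpha, triangles = triangles,
                             impostors = impostors,
                             alphabet = pool@alphabet, width = pool@width,
                             pool = prof)),
            class = "coreLP")
}

# triangle rows for one (class, position) block, as pair-variable offsets:
# sigma(p,r) - sigma(p,q) - sigma(q,r) <= 0 for p < r, q not in {p, r}
.triangleTriples <- function(ns) {
  lay <- .pairLayout(ns)
  pr <- which(upper.tri(matrix(0, ns, ns)), arr.ind = TRUE)
  p <- rep(pr[, 1L], each = ns - 2L)
  r <- rep(pr[, 2L], each = ns - 2L)
  q <- as.vector(vapply(seq_len(nrow(pr)), function(t)
    setdiff(seq_len(ns), c(pr[t, 1L], pr[t, 2L])), integer(ns - 2L)))
  n <- length(p)
  keep <- !is.na(lay$idx[cbind(p, r)])  # always true (p < r), kept for safety
  p <- p[keep]; q <- q[keep]; r <- r[keep]; n <- length(p)
  rows <- rep(seq_len(n), 3L)
  cols <- c(lay$idx[cbind(p, r)], lay$idx[cbind(p, q)], lay$idx[cbind(q, r)])
  vals <- c(rep(1, n), rep(-1, n), rep(-1, n))
  # (gap,gap) has no variable: drop those coefficient entries
  drop <- is.na(cols)
  list(rows = rows[!drop], cols = cols[!drop], vals = vals[!drop],
       triples = data.frame(p = p, q = q, r = r))
}

# add triangle rows for specific violated triples of one (class, position)
.addTriangleRows <- function(lp, ci, i, triples) {
  lay <- lp$meta$lay; np <- lay$n; P <- lp$meta$P
  off <- (ci - 1L) * P * np + (i - 1L) * np
  n <- nrow(triples)
  cols <- off + c(lay$idx[cbind(triples$p, triples$r)],
                  lay$idx[cbind(triples$p, triples$q)],
                  lay$idx[cbind(triples$q, triples$r)])
  vals <- c(rep(1, n), rep(-1, n), rep(-1, n))
  rows <- lp$nRows + rep(seq_len(n), 3L)
  keep <- !is.na(cols)
  lp$i <- c(lp$i, rows[keep]); lp$j <- c(lp$j, cols[keep])
  lp$v <- c(lp$v, vals[keep]); lp$b <- c(lp$b, rep(0, n))
  lp$nRows <- lp$nRows + n
  lp
}

# reconstruct the DistanceModel from an LP solution vector; solver roundoff
# below the bound is clipped to zero
.modelFromX <- function(lp, x) {
  x <- pmax(x, 0)
  m <- lp$meta
  lay <- m$lay; np <- lay$n; ns <- m$ns; P <- m$P
  sigma <- list()
  for (ci in seq_along(.STRUCTURED_CLASSES)) {
    a <- array(0, dim = c(ns, ns, P))
    for (i in seq_len(P)) {
      vals <- x[(ci - 1L) * P * np + (i - 1L) * np + seq_len(np)]
      M <- matrix(0, ns, ns)
      M[cbind(lay$pu, lay$qu)] <- vals
      M[cbind(lay$qu, lay$pu)] <- vals
      a[, , i] <- M
    }
    sigma[[.STRUCTURED_CLASSES[ci]]] <- a
  }
  new("DistanceModel", sigma = sigma, tau = max(x[m$tauIdx], 0),
      width = m$width, alphabet = m$alphabet)
}

# worst score-level triangle violations of a model; returns per (class,
# position) the violated triples beyond tol, at the minimizing witness q
.triangleViolations <- function(model, tol = 1e-6, maxPerBlock = 500L) {
  ns <- nStates(model@alphabet)
  P <- 2L * model@width + 1L
  out <- list()
  for (ci in seq_along(.STRUCTURED_CLASSES)) {
    for (i in seq_len(P)) {
      M <- model@sigma[[.STRUCTURED_CLASSES[ci]]][, , i]
      stacks <- lapply(seq_len(ns), function(q) outer(M[, q], M[q, ], `+`))
      best <- Reduce(pmin, stacks)
      viol <- M - best
      hit <- which(viol > tol & upper.tri(viol), arr.ind = TRUE)
      if (!nrow(hit)) next
      o <- order(viol[hit], decreasing = TRUE)
      hit <- hit[utils::head(o, maxPerBlock), , drop = FALSE]
      qstar <- vapply(seq_len(nrow(hit)), function(t) {
        p <- hit[t, 1L]; r <- hit[t, 2L]
        sums <- M[p, ] + M[, r]
        sums[c(p, r)] <- Inf
        which.min(sums)
      }, integer(1))
      out[[length(out) + 1L]] <- list(ci = ci, i = i,
        triples = data.frame(p = hit[, 1L], q = qstar, r = hit[, 2L],
                             violation = viol[hit]))
    }
  }
  out
}

# distances for specific (W, V) window pairs under one class's tables
.pairDist <- function(model, class, Wm, Vm) {
  sig <- model@sigma[[class]]
  ns <- nStates(model@alphabet)
  P <- 2L * model@width + 1L
  d <- numeric(nrow(Wm))
  for (i in seq_len(P))
    d <- d + rowSums((.posBlock(Wm, i, ns) %*% sig[, , i]) *
                       .posBlock(Vm, i, ns))
  d
}

# distances of every impostor pair recorded in the LP's impostor map
.impostorDistances <- function(lp, model) {
  m <- lp$meta
  d <- numeric(nrow(m$impMap))
  for (bl in unique(m$impMap$bClass)) {
    sel <- m$impMap$bClass == bl
    d[sel] <- .pairDist(model, bl,
                        m$pool[m$impMap$W[sel], , drop = FALSE],
                        m$pool[m$impMap$V[sel], , drop = FALSE])
  }
  d
}

# append specific impostor rows (indices into meta$impMap) to the LP
.addImpostorRows <- function(lp, which) {
  m <- lp$meta
  lay <- m$lay; np <- lay$n
  im <- m$impMap[which, , drop = FALSE]
  for (bl in unique(im$bClass)) {
    sel <- which(im$bClass == bl)
    bi <- match(bl, .STRUCTURED_CLASSES)
    coef <- .pairCoef(m$pool[im$W[sel], , drop = FALSE],
                      m$pool[im$V[sel], , drop = FALSE], m$ns, m$P, lay)
    n <- length(sel)
    rows <- lp$nRows + rep(seq_len(n), m$P * np + 2L)
    cols <- c(rep((bi - 1L) * m$P * np + seq_len(m$P * np), each = n),
              rep(m$tauIdx, n), im$fVar[sel])
    vals <- c(-as.vector(coef), rep(1, n), rep(-1, n))
    keep <- vals != 0
    lp$i <- c(lp$i, rows[keep]); lp$j <- c(lp$j, cols[keep])
    lp$v <- c(lp$v, vals[keep]); lp$b <- c(lp$b, rep(-1, n))
    lp$nRows <- lp$nRows + n
  }
  lp
}

#' Solve the distance-learning LP
#'
#' Solves through the sparse HiGHS backend. Constraint families built as
#' deferred ("none"/"lazy") are generated by cutting planes: solve, find
#' violated triangle triples and violated impostor rows (for each impostor
#' error variable, the most violated absent row per impostor class), add
#' them, re-solve, until no violation beyond \code{tol} remains. The final
#' clean scan over all state triples and all impostor pairs is the
#' convergence certificate; the optimum equals the fully enumerated LP's.
#'
#' @param lp a \code{"coreLP"} object
#' @param tol violation tolerance for cutting-plane generation
#' @param maxRounds cap on re-solve rounds
#' @return a list with the fitted \linkS4class{DistanceModel}, error
#'   variables \code{e} and \code{f} (named by constraint), the objective
#'   value, solver status, and an \code{info} list (rounds, added row
#'   counts, final triangle violation)
#' @export
solveDistanceLP <- function(lp, tol = 1e-6, maxRounds = 200L) {
  lazyTri <- lp$meta$triangles == "none"
  lazyImp <- identical(lp$meta$impostors, "lazy")
  m <- lp$meta
  impAdded <- logical(nrow(m$impMap))
  impKey <- paste(m$impMap$fVar, m$impMap$bClass)
  rounds <- 0L; addedRows <- 0L
  repeat {
    sol <- .solveLP(lp$i, lp$j, lp$v, lp$b, lp$obj, lp$nRows, lp$nCols)
    model <- .modelFromX(lp, sol$x)
    grew <- FALSE
    if (lazyImp) {
      dImp <- .impostorDistances(lp, model)
      viol <- (model@tau - dImp + 1) - sol$x[m$impMap$fVar]
      cand <- if (max(viol) > tol) which(viol > tol / 2 & !impAdded) else
        integer(0)
      if (length(cand)) {
        o <- cand[order(-viol[cand])]
        pick <- o[!duplicated(impKey[o])]
        lp <- .addImpostorRows(lp, pick)
        impAdded[pick] <- TRUE
        addedRows <- addedRows + length(pick)
        grew <- TRUE
      }
    }
    if (lazyTri) {
      tv <- .triangleViolations(model, tol / 2)
      if (length(tv) &&
          max(vapply(tv, function(v) max(v$triples$violation), 0)) > tol) {
        for (vb in tv)
          lp <- .addTriangleRows(lp, vb$ci, vb$i, vb$triples)
        addedRows <- addedRows + sum(vapply(tv, function(v)
          nrow(v$triples), 1L))
        grew <- TRUE
      }
    }
    if (!grew) break
    rounds <- rounds + 1L
    if (rounds > maxRounds)
      stop("cutting-plane generation did not converge in ", maxRounds,
           " rounds")
  }
  e <- sol$x[m$eMap$var]
  fAll <- do.call(rbind, m$fMap)
  f <- sol$x[fAll$var]
  finalViol <- verifyTriangle(model, nTriples = 0L)$sigmaMaxViolation
  list(model = model, e = e, f = f, objective = sol$objective,
       status = sol$status, x = sol$x,
       info = list(lazyRounds = rounds, addedRows = addedRows,
                   triangleViolation = finalViol,
                   certified = finalViol <= tol))
}

#' Re-check an LP solution outside the solver
#'
#' Recomputes every constraint family from the returned score tables and
#' threshold: target and impostor inequalities, the identities
#' e = max(d_c(V,W) - tau, 0) and f = max over impostors of
#' (tau - d_b(V,W) + 1, 0), self-dissimilarity, non-negativity, and the
#' score-level triangle inequality.
#'
#' @param lp the \code{"coreLP"} the solution came from
#' @param sol result of \code{\link{solveDistanceLP}}
#' @param tol feasibility tolerance
#' @return list of maximal violations per family, plus \code{ok}
#' @export
checkLPSolution <- function(lp, sol, tol = 1e-6) {
  m <- lp$meta
  model <- sol$model
  tau <- model@tau
  prof <- m$pool
  dOf <- function(cl, wIdx, vIdx) {
    vapply(seq_along(wIdx), function(r)
      windowDistance(model, cl, prof[wIdx[r], ], prof[vIdx[r], ]),
      numeric(1))
  }
  dT <- numeric(0)
  eErr <- 0
  for (cl in unique(m$eMap$class)) {
    sel <- m$eMap$class == cl
    d <- dOf(cl, m$eMap$W[sel], m$eMap$V[sel])
    eErr <- max(eErr, max(abs(sol$x[m$eMap$var[sel]] - pmax(d - tau, 0))))
  }
  # f identity: max over each f variable's impostor rows
  dImp <- numeric(nrow(m$impMap))
  for (bl in unique(m$impMap$bClass)) {
    sel <- m$impMap$bClass == bl
    dImp[sel] <- dOf(bl, m$impMap$W[sel], m$impMap$V[sel])
  }
  fErr <- 0; impFeas <- 0
  for (fv in unique(m$impMap$fVar)) {
    sel <- m$impMap$fVar == fv
    want <- max(c(tau - dImp[sel] + 1, 0))
    fErr <- max(fErr, abs(sol$x[fv] - want))
    impFeas <- max(impFeas, max(tau - dImp[sel] + 1 - sol$x[fv]))
  }
  tri <- verifyTriangle(model, nTriples = 0L)$sigmaMaxViolation
  selfErr <- 0; negErr <- 0
  ns <- m$ns
  for (cl in .STRUCTURED_CLASSES) for (i in seq_len(m$P)) {
    M <- model@sigma[[cl]][, , i]
    selfErr <- max(selfErr,
                   max(outer(diag(M)[-ns], rep(1, ns)) - M[-ns, , drop = FALSE]))
    negErr <- max(negErr, -min(M))
  }
  out <- list(eIdentity = eErr, fIdentity = fErr,
              impostorFeasibility = max(impFeas, 0),
              triangle = tri, selfDissim = max(selfErr, 0),
              negativity = max(negErr, 0), tau = -min(tau, 0))
  out$ok <- all(unlist(out) <= tol)
  out
}

#' Learn a distance model from assembled window sets
#'
#' Convenience wrapper: build neighborhoods, build the LP, solve it (with
#' exhaustively enumerated or lazily generated triangle constraints), and
#' verify feasibility.
#'
#' @inheritParams buildNeighborhoods
#' @inheritParams buildDistanceLP
#' @param triangles "full" or "lazy"
#' @param tol feasibility/violation tolerance
#' @return as \code{\link{solveDistanceLP}}, plus the \code{lp},
#'   neighborhoods and the feasibility report under \code{check}
#' @export
trainDistanceModel <- function(sets, mode = c("random", "default", "model"),
                               k = 2L, l = 150L, alpha = 0.5, seed = 1L,
                               model = NULL, triangles = c("lazy", "full"),
                               impostors = c("lazy", "all"),
                               tol = 1e-6) {
  mode <- match.arg(mode)
  triangles <- match.arg(triangles)
  impostors <- match.arg(impostors)
  nbhd <- buildNeighborhoods(sets, mode, k = k, l = l, seed = seed,
                             model = model)
  lp <- buildDistanceLP(sets, nbhd, alpha = alpha,
                        triangles = if (triangles == "full") "full" else "none",
                        impostors = impostors)
  sol <- solveDistanceLP(lp, tol = tol)
  sol$check <- checkLPSolution(lp, sol, tol = max(tol, 1e-5))
  sol$lp <- lp
  sol$neighborhoods <- nbhd
  sol
}

#' Iterated distance learning
#'
#' Iteration 1 builds neighborhoods with the requested starting mode;
#' every later iteration rebuilds them under the previous iteration's
#' learned model. Per-iteration training and testing AUCs come from the
#' coreness regressor fitted to that iteration's model.
#'
#' @inheritParams trainDistanceModel
#' @param nIters number of LP iterations (>= 1)
#' @param startMode neighborhoods mode of the first iteration
#' @param ell bracket count for the logistic transform fitting
#' @return list with \code{models} (one per iteration) and \code{auc}, a
#'   data.frame of training and testing AUC per iteration
#' @export
iterateTraining <- function(sets, nIters = 1L,
                            startMode = c("default", "random"),
                            k = 2L, l = 150L, alpha = 0.5, seed = 1L,
                            ell = 20L, triangles = c("lazy", "full"),
                            tol = 1e-6) {
  startMode <- match.arg(startMode)
  triangles <- match.arg(triangles)
  stopifnot(nIters >= 1L)
  models <- vector("list", nIters)
  auc <- data.frame(iteration = seq_len(nIters), train = NA_real_,
                    test = NA_real_)
  prev <- NULL
  for (it in seq_len(nIters)) {
    sol <- trainDistanceModel(sets,
                              mode = if (it == 1L) startMode else "model",
                              k = k, l = l, alpha = alpha, seed = seed + it,
                              model = prev, triangles = triangles, tol = tol)
    reg <- buildCorenessRegressor(sol$model, sets, ell = ell)
    trainIdx <- unlist(sets@Sc, use.names = FALSE)
    auc$train[it] <- .regressorAUC(reg, sets@pool, trainIdx)
    auc$test[it] <- .regressorAUC(reg, sets@pool, sets@test)
    models[[it]] <- sol$model
    prev <- sol$model
  }
  list(models = models, auc = auc)
}
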