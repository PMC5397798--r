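# distances are compared at 1e-9 resolution wherever ties matter, so that
# floating-point noise between equivalent computations (e.g. duplicated
# windows evaluated in different BLAS call shapes) cannot flip a tie-break
.quantize <- function(d) round(d * 1e9)

# view of position i's block of a flattened window matrix
.posBlock <- function(mat, i, ns) {
  mat[, ((i - 1L) * ns + 1L):(i * ns), drop = FALSE]
}

.checkWidth <- function(model, v) {
  P <- 2L * model@width + 1L
  ns <- nStates(model@alphabet)
  if (length(v) != P * ns)
    stop("window width mismatch: expected ", P * ns, " values, got ",
         length(v))
}

#' Class-specific distance between two windows
#'
#' d_c(V, W) = sum over positions i and state pairs (p, q) of
#' V_i(p) W_i(q) sigma_{c,i}(p, q). Bilinear in the two profiles and
#' symmetric because the score tables are symmetric.
#'
#' @param model a \linkS4class{DistanceModel}
#' @param class a structured window class
#' @param V,W flattened window vectors (as rows of a WindowSet)
#' @return non-negative distance
#' @export
windowDistance <- function(model, class, V, W) {
  .checkWidth(model, V); .checkWidth(model, W)
  sig <- model@sigma[[class]]
  if (is.null(sig)) stop("unknown structured class: ", class)
  ns <- nStates(model@alphabet)
  P <- 2L * model@width + 1L
  d <- 0
  for (i in seq_len(P)) {
    vi <- V[((i - 1L) * ns + 1L):(i * ns)]
    wi <- W[((i - 1L) * ns + 1L):(i * ns)]
    d <- d + drop(vi %*% sig[, , i] %*% wi)
  }
  d
}

#' All pairwise distances between two window sets
#'
#' @param model DistanceModel
#' @param class structured class whose distance applies
#' @param A,B numeric matrices of flattened windows (rows)
#' @return |A| x |B| distance matrix
#' @export
windowCrossDist <- function(model, class, A, B) {
  sig <- model@sigma[[class]]
  ns <- nStates(model@alphabet)
  P <- 2L * model@width + 1L
  D <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(P))
    D <- D + .posBlock(A, i, ns) %*% sig[, , i] %*% t(.posBlock(B, i, ns))
  D
}

# BLOSUM62 similarity rescaled to a [0,1] dissimilarity over the 20 amino
# acids, diagonal forced to zero so identical point-mass states are at
# distance zero
.blosumDissim <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  s <- e$BLOSUM62[.AA20, .AA20]
  d <- (max(s) - s) / (max(s) - min(s))
  diag(d) <- 0
  d
}

#' Default bootstrap window distance
#'
#' The distance used to seed LP neighborhoods before any learning: the
#' positional substitution score is a convex mix of a [0,1]-rescaled
#' amino-acid substitution dissimilarity and the identity function on
#' secondary-structure types, with the center column given twice the weight
#' of its flanks (weights normalized to sum to 1). Gap handling:
#' score(gap, gap) = 0, score(gap, non-gap) = 1. For reduced alphabets the
#' residue dissimilarity is averaged over group members. Returned as a
#' \linkS4class{DistanceModel} with identical tables for every class, so all
#' distance machinery applies unchanged.
#'
#' @param alphabet StateAlphabet
#' @param w window half-width
#' @param gammaMix weight on the amino-acid term (1 - gammaMix on the
#'   secondary-structure identity term)
#' @param dissim optional 20x20 amino-acid dissimilarity matrix in [0,1]
#'   (rows/columns named by amino acid); defaults to rescaled BLOSUM62
#' @return a DistanceModel (tau = 0; the threshold is unused here)
#' @export
defaultDistanceModel <- function(alphabet = stateAlphabet("full"), w = 1L,
                                 gammaMix = 0.5, dissim = NULL) {
  stopifnot(gammaMix >= 0, gammaMix <= 1)
  w <- as.integer(w)
  if (is.null(dissim)) dissim <- .blosumDissim()
  res <- alphabet@residues
  nr <- length(res)
  # residue-group dissimilarity: mean over member pairs
  gdis <- matrix(0, nr, nr)
  for (a in seq_len(nr)) for (b in seq_len(nr)) {
    ma <- names(alphabet@groups)[alphabet@groups == res[a]]
    mb <- names(alphabet@groups)[alphabet@groups == res[b]]
    gdis[a, b] <- mean(dissim[ma, mb])
  }
  if (alphabet@name == "full") diag(gdis) <- 0
  ns <- nStates(alphabet)
  S <- matrix(1, ns, ns)   # gap vs non-gap: maximal dissimilarity
  for (a in seq_len(nr)) for (b in seq_len(nr)) for (si in 1:3) for (sj in 1:3)
    S[(a - 1L) * 3L + si, (b - 1L) * 3L + sj] <-
      gammaMix * gdis[a, b] + (1 - gammaMix) * (si != sj)
  S[ns, ns] <- 0
  P <- 2L * w + 1L
  wts <- rep(1, P); wts[w + 1L] <- 2; wts <- wts / sum(wts)
  sig <- lapply(.STRUCTURED_CLASSES, function(cl) {
    a <- array(0, dim = c(ns, ns, P))
    for (i in seq_len(P)) a[, , i] <- wts[i] * S
    a
  })
  names(sig) <- .STRUCTURED_CLASSES
  new("DistanceModel", sigma = sig, tau = 0, width = w, alphabet = alphabet)
}

#' Verify the triangle inequality of a distance model
#'
#' Checks (a) the score-level triangle sigma(p,r) <= sigma(p,q) + sigma(q,r)
#' exhaustively over all state triples for every class and position, and
#' (b) the window-level triangle d_c(U,W) <= d_c(U,V) + d_c(V,W) on random
#' window triples (random per-position distributions over states). The
#' window-level violation can never exceed the score-level one (the
#' window distance is a convex combination of score-level triangles).
#'
#' @param model DistanceModel
#' @param nTriples number of random window triples
#' @param seed RNG seed
#' @param tol tolerance for declaring a violation
#' @param windows optional WindowSet to draw triples from instead of random
#'   profiles
#' @return list with fields sigmaMaxViolation, windowMaxViolation, ok
#' @export
verifyTriangle <- function(model, nTriples = 1000L, seed = 1L, tol = 1e-6,
                           windows = NULL) {
  ns <- nStates(model@alphabet)
  P <- 2L * model@width + 1L
  sigmaMax <- -Inf
  for (cl in .STRUCTURED_CLASSES) {
    for (i in seq_len(P)) {
      M <- model@sigma[[cl]][, , i]
      best <- Reduce(pmin, lapply(seq_len(ns),
                                  function(q) outer(M[, q], M[q, ], `+`)))
      sigmaMax <- max(sigmaMax, max(M - best))
    }
  }
  drawWindow <- function() {
    v <- numeric(P * ns)
    for (i in seq_len(P)) {
      x <- stats::rgamma(ns, 1)
      v[((i - 1L) * ns + 1L):(i * ns)] <- x / sum(x)
    }
    v
  }
  windowMax <- -Inf
  .withSeed(seed, {
    for (t in seq_len(nTriples)) {
      cl <- .STRUCTURED_CLASSES[(t - 1L) %% 5L + 1L]
      if (is.null(windows)) {
        U <- drawWindow(); V <- drawWindow(); W <- drawWindow()
      } else {
        idx <- sample.int(nrow(windows@profiles), 3L, replace = TRUE)
        U <- windows@profiles[idx[1L], ]
        V <- windows@profiles[idx[2L], ]
        W <- windows@profiles[idx[3L], ]
      }
      viol <- windowDistance(model, cl, U, W) -
        windowDistance(model, cl, U, V) - windowDistance(model, cl, V, W)
      windowMax <- max(windowMax, viol)
    }
  })
  list(sigmaMaxViolation = sigmaMax, windowMaxViolation = windowMax,
       nTriples = nTriples, tol = tol,
       ok = sigmaMax <= tol)
}

## ---- exact metric nearest-neighbor index (vantage-point tree) ------------

.VP_LEAF <- 8L

.buildVPNode <- function(data, model, class, idx) {
  if (length(idx) <= .VP_LEAF) return(list(bucket = idx))
  vp <- idx[1L]                      # deterministic vantage point
  rest <- idx[-1L]
  d <- drop(windowCrossDist(model, class, data[vp, , drop = FALSE],
                            data[rest, , drop = FALSE]))
  r <- stats::median(d)
  inner <- rest[d <= r]
  outer <- rest[d > r]
  if (!length(inner) || !length(outer))   # degenerate split: bucket it
    return(list(bucket = idx))
  list(vp = vp, radius = r,
       inner = .buildVPNode(data, model, class, inner),
       outer = .buildVPNode(data, model, class, outer))
}

#' Build an exact nearest-neighbor index for one class
#'
#' A vantage-point tree with exact metric pruning. The model's score tables
#' are verified for the triangle inequality first; on violation beyond the
#' tolerance the index falls back to brute-force scanning (with a warning),
#' so queries stay exact either way. Ties are broken by insertion order.
#'
#' @param Tc numeric matrix of flattened training windows (rows)
#' @param model DistanceModel
#' @param class structured class whose distance indexes Tc
#' @param tol triangle-verification tolerance
#' @return an \linkS4class{NNIndex}
#' @export
buildNNIndex <- function(Tc, model, class, tol = 1e-6) {
  stopifnot(nrow(Tc) >= 1L)
  chk <- verifyTriangle(model, nTriples = 0L)
  brute <- FALSE
  if (chk$sigmaMaxViolation > tol) {
    warning("score tables violate the triangle inequality (max ",
            format(chk$sigmaMaxViolation), "); using brute-force search")
    brute <- TRUE
  }
  tree <- if (brute) list() else
    .buildVPNode(Tc, model, class, seq_len(nrow(Tc)))
  new("NNIndex", data = Tc, tree = tree, model = model, wclass = class,
      brute = brute)
}

#' Query an NN index for the i nearest neighbors
#'
#' Exact: results are identical to a brute-force scan, with ties broken by
#' insertion order.
#'
#' @param index an NNIndex
#' @param W flattened query window
#' @param i number of neighbors
#' @return list with \code{index} and \code{distance}, sorted by
#'   (distance, insertion order)
#' @export
nnQuery <- function(index, W, i = 1L) {
  n <- nrow(index@data)
  i <- min(i, n)
  distTo <- function(idx) {
    drop(windowCrossDist(index@model, index@wclass,
                         matrix(W, 1L), index@data[idx, , drop = FALSE]))
  }
  if (index@brute) {
    d <- distTo(seq_len(n))
    o <- order(.quantize(d), seq_len(n))[seq_len(i)]
    return(list(index = o, distance = d[o]))
  }
  # the candidate pool keeps everything within eps of the i-th best, and the
  # final ranking recomputes the pool's distances in one batch call, so
  # duplicated windows tie bitwise and insertion order decides
  eps <- 1e-9
  bd <- numeric(0); bi <- integer(0)
  worst <- function() {
    if (length(bd) < i) return(Inf)
    sort(bd, partial = i)[i]
  }
  push <- function(d, idx) {
    bd <<- c(bd, d); bi <<- c(bi, idx)
    if (length(bd) > 4L * i) {
      thr <- worst() + eps
      keep <- bd <= thr
      bd <<- bd[keep]; bi <<- bi[keep]
    }
  }
  visit <- function(node) {
    if (!is.null(node$bucket)) {
      d <- distTo(node$bucket)
      for (j in seq_along(d)) push(d[j], node$bucket[j])
      return(invisible())
    }
    dvp <- distTo(node$vp)
    push(dvp, node$vp)
    if (dvp <= node$radius) {
      visit(node$inner)
      if (node$radius - dvp <= worst() + eps) visit(node$outer)
    } else {
      visit(node$outer)
      if (dvp - node$radius <= worst() + eps) visit(node$inner)
    }
  }
  visit(index@tree)
  pool <- sort(unique(bi))
  dFinal <- distTo(pool)
  o <- order(.quantize(dFinal), pool)[seq_len(min(i, length(pool)))]
  list(index = pool[o], distance = dFinal[o])
}

#' Nearest structured-class training window
#'
#' Queries one index per structured class and keeps the globally smallest
#' distance; ties between classes go to the earlier class in the fixed
#' order CCC, CCN, NCC, CNN, NNC (then insertion order within a class).
#'
#' @param indices named list of NNIndex objects, one per structured class
#' @param W flattened query window
#' @return list with \code{class}, \code{index} (within that class's set)
#'   and \code{distance}
#' @export
nearestStructured <- function(indices, W) {
  if (!all(.STRUCTURED_CLASSES %in% names(indices)))
    stop("need one index per structured class")
  best <- NULL
  for (cl in .STRUCTURED_CLASSES) {
    r <- nnQuery(indices[[cl]], W, 1L)
    if (is.null(best) || .quantize(r$distance[1L]) < .quantize(best$distance)) {
      best <- list(class = cl, index = r$index[1L],
                   distance = r$distance[1L])
    }
  }
  best
}

# batch nearest-structured search by dense cross-distance (same result as
# per-query index search: exact minima, first-index/first-class ties)
.nearestStructuredBatch <- function(model, trainSets, Q) {
  nq <- nrow(Q)
  dmin <- matrix(Inf, nq, length(.STRUCTURED_CLASSES))
  imin <- matrix(NA_integer_, nq, length(.STRUCTURED_CLASSES))
  for (ci in seq_along(.STRUCTURED_CLASSES)) {
    cl <- .STRUCTURED_CLASSES[ci]
    D <- windowCrossDist(model, cl, Q, trainSets[[cl]])
    imin[, ci] <- max.col(-.quantize(D), ties.method = "first")
    dmin[, ci] <- D[cbind(seq_len(nq), imin[, ci])]
  }
  pick <- max.col(-.quantize(dmin), ties.method = "first")
  data.frame(class = .STRUCTURED_CLASSES[pick],
             distance = dmin[cbind(seq_len(nq), pick)],
             index = imin[cbind(seq_len(nq), pick)])
}

setMethod("show", "NNIndex", function(object) {
  cat(sprintf("NNIndex (%s): %d windows, class %s%s\n",
              if (object@brute) "brute-force" else "vp-tree",
              nrow(object@data), object@wclass,
              if (object@brute) " [triangle verification failed]" else ""))
})

setMethod("show", "DistanceModel", function(object) {
  cat(sprintf("DistanceModel: width %d, alphabet '%s' (%d states), tau = %.4g\n",
              object@width, object@alphabet@name, nStates(object@alphabet),
              object@tau))
})
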