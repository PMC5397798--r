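#' Empirical distance-to-coreness curve
#'
#' Examples are sorted by nearest-neighbor distance; at each distinct
#' distance the average true coreness is taken over all examples tied at
#' that distance plus the ell examples immediately below and the ell
#' immediately above it (truncated at either end).
#'
#' @param delta nearest-neighbor distances
#' @param coreness true coreness of the same examples
#' @param ell bracket count on each side
#' @return data.frame with columns \code{delta}, \code{avg}, \code{n}
#' @export
empiricalCurve <- function(delta, coreness, ell = 100L) {
  stopifnot(length(delta) == length(coreness), length(delta) >= 1L,
            ell >= 0L)
  o <- order(delta)
  d <- delta[o]; cr <- coreness[o]
  ud <- unique(d)
  avg <- numeric(length(ud)); n <- integer(length(ud))
  for (i in seq_along(ud)) {
    ties <- which(d == ud[i])
    lo <- max(min(ties) - ell, 1L)
    hi <- min(max(ties) + ell, length(d))
    take <- lo:hi
    avg[i] <- mean(cr[take])
    n[i] <- length(take)
  }
  data.frame(delta = ud, avg = avg, n = n)
}

#' Evaluate a logistic transform
#' @param transform a \linkS4class{LogisticTransform}
#' @param x distances
#' @export
evalLogistic <- function(transform, x) {
  if (transform@degenerate) return(rep(transform@kappa, length(x)))
  transform@kappa + (transform@lambda - transform@kappa) /
    (1 + exp(-transform@slope * (x - transform@inflection)))
}

#' Fit a logistic distance-to-coreness transform
#'
#' The floor and ceiling are fixed to the minimum and maximum of the
#' curve points' average coreness; slope and inflection are fitted by
#' nonlinear least squares under an explicit monotonicity constraint
#' (the slope's sign is fixed by \code{orientation}), so the fitted curve
#' is decreasing for the core transform and increasing for the non-core
#' one regardless of parameter-sign conventions. By construction the curve
#' passes through the floor/ceiling midpoint at its inflection.
#'
#' @param points data.frame from \code{\link{empiricalCurve}} (columns
#'   \code{delta}, \code{avg}), or any frame with those columns
#' @param orientation "decreasing" or "increasing"
#' @return a \linkS4class{LogisticTransform}
#' @export
fitLogistic <- function(points, orientation = c("decreasing", "increasing")) {
  orientation <- match.arg(orientation)
  stopifnot(nrow(points) >= 4L)
  x <- points$delta; y <- points$avg
  kap <- min(y); lam <- max(y)
  if (lam - kap < 1e-12)
    return(new("LogisticTransform", kappa = kap, lambda = lam, slope = 0,
               inflection = stats::median(x), degenerate = TRUE))
  sgn <- if (orientation == "decreasing") -1 else 1
  span <- max(diff(range(x)), 1e-8)
  sse <- function(u, beta) {
    pred <- kap + (lam - kap) / (1 + exp(-(sgn * exp(u)) * (x - beta)))
    sum((y - pred)^2)
  }
  starts <- expand.grid(u = log(c(1, 4, 16) / span),
                        beta = stats::quantile(x, c(0.25, 0.5, 0.75),
                                               names = FALSE))
  fit <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ kap + (lam - kap) / (1 + exp(-(sgn * exp(u)) * (x - beta))),
        start = list(u = starts$u[s], beta = starts$beta[s]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    return(new("LogisticTransform", kappa = kap, lambda = lam,
               slope = sgn * exp(cf[["u"]]), inflection = cf[["beta"]]))
  }
  # least-squares surface is ill-conditioned (e.g. near-constant points):
  # fall back to a coarse grid minimizer, which always yields a usable
  # monotone transform
  grid <- expand.grid(u = seq(log(0.1 / span), log(100 / span),
                              length.out = 25),
                      beta = stats::quantile(x, seq(0.02, 0.98,
                                                    length.out = 25),
                                             names = FALSE))
  err <- mapply(sse, grid$u, grid$beta)
  bestG <- which.min(err)
  new("LogisticTransform", kappa = kap, lambda = lam,
      slope = sgn * exp(grid$u[bestG]), inflection = grid$beta[bestG])
}

setMethod("show", "LogisticTransform", function(object) {
  if (object@degenerate)
    cat(sprintf("LogisticTransform: constant %.4g (degenerate)\n",
                object@kappa))
  else
    cat(sprintf(
      "LogisticTransform: floor %.4g, ceiling %.4g, slope %.4g, inflection %.4g\n",
      object@kappa, object@lambda, object@slope, object@inflection))
})

# rebuild vp-tree indices of a regressor (e.g. after deserialization)
rebuildIndices <- function(reg) {
  reg@indices <- lapply(.STRUCTURED_CLASSES, function(cl)
    buildNNIndex(reg@train[[cl]], reg@model, cl))
  names(reg@indices) <- .STRUCTURED_CLASSES
  reg
}

#' Assemble the coreness regressor
#'
#' Builds per-class nearest-neighbor indices over the structured training
#' windows, computes nearest-structured-class distances for a broad sample
#' of training-fold example windows (all classes, the unstructured one
#' included, so the curves see low-coreness examples at every distance),
#' splits them by whether the nearest class is core or non-core, forms the
#' empirical average-coreness curves, and fits the two logistic transforms
#' (decreasing f_core, increasing f_non).
#'
#' @param model a learned \linkS4class{DistanceModel}
#' @param sets the \linkS4class{WindowSets} used in training
#' @param ell bracket count for the empirical curve
#' @param maxExamples cap on the number of transform-fitting examples
#'   (seeded subsample of the training-fold windows)
#' @return a \linkS4class{CorenessRegressor}
#' @export
buildCorenessRegressor <- function(model, sets, ell = 100L,
                                   maxExamples = 4000L) {
  pool <- sets@pool
  train <- lapply(sets@Tc, function(idx) pool@profiles[idx, , drop = FALSE])
  exIdx <- sets@trainPool
  if (!length(exIdx))
    exIdx <- c(unlist(sets@Sc, use.names = FALSE), sets@bottom)
  if (length(exIdx) > maxExamples)
    exIdx <- .withSeed(sets@seed,
                       sort(exIdx[sample.int(length(exIdx), maxExamples)]))
  near <- .nearestStructuredBatch(model, train,
                                  pool@profiles[exIdx, , drop = FALSE])
  trueCor <- pool@info$coreness[exIdx]
  isCore <- near$class %in% .CORE_CLASSES
  fitSide <- function(sel, orientation) {
    if (sum(sel) < 4L)
      stop("too few examples (", sum(sel), ") to fit the ", orientation,
           " transform")
    pts <- empiricalCurve(near$distance[sel], trueCor[sel], ell)
    if (nrow(pts) < 4L) {
      # very few distinct distances: fall back to raw (delta, coreness) pairs
      pts <- data.frame(delta = near$distance[sel], avg = trueCor[sel])
    }
    fitLogistic(pts, orientation)
  }
  fCore <- fitSide(isCore, "decreasing")
  fNon <- fitSide(!isCore, "increasing")
  reg <- new("CorenessRegressor", model = model, train = train,
             indices = list(), fCore = fCore, fNon = fNon)
  rebuildIndices(reg)
}

#' Predict the coreness of a window
#'
#' Finds the nearest structured-class training window (metric NN search
#' across the five class indices), then transforms the distance through
#' f_core if the nearest class is core, f_non otherwise; the result is
#' clamped to [0, 1].
#'
#' @param regressor a \linkS4class{CorenessRegressor}
#' @param W flattened window vector
#' @return predicted coreness in [0, 1]
#' @export
predictCoreness <- function(regressor, W) {
  .checkWidth(regressor@model, W)
  hit <- nearestStructured(regressor@indices, W)
  f <- if (hit$class %in% .CORE_CLASSES) regressor@fCore else regressor@fNon
  min(max(evalLogistic(f, hit$distance), 0), 1)
}

# batch prediction over the rows of a WindowSet (dense search, same result)
predictWindows <- function(regressor, windows,
                           idx = seq_len(nrow(windows@profiles))) {
  near <- .nearestStructuredBatch(regressor@model, regressor@train,
                                  windows@profiles[idx, , drop = FALSE])
  isCore <- near$class %in% .CORE_CLASSES
  out <- numeric(length(idx))
  out[isCore] <- evalLogistic(regressor@fCore, near$distance[isCore])
  out[!isCore] <- evalLogistic(regressor@fNon, near$distance[!isCore])
  pmin(pmax(out, 0), 1)
}

#' Per-column coreness predictions for an alignment
#'
#' @param regressor a \linkS4class{CorenessRegressor}
#' @param alignment a ProteinAlignment
#' @param ss per-sequence secondary-structure confidences
#' @return numeric vector, one predicted coreness per column
#' @export
predictAlignment <- function(regressor, alignment, ss) {
  ws <- extractWindows(alignment, ss, regressor@model@width,
                       regressor@model@alphabet)
  predictWindows(regressor, ws)
}

#' Rank-based classification AUC
#'
#' Area under the ROC curve via the Mann-Whitney statistic; ties count one
#' half.
#'
#' @param scores numeric prediction scores
#' @param labels logical (or two-valued) labels; TRUE/larger = positive
#' @return AUC in [0, 1]
#' @export
classificationAUC <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both label values must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.regressorAUC <- function(regressor, pool, idx) {
  pred <- predictWindows(regressor, pool, idx)
  classificationAUC(pred, pool@info$label[idx] == "C")
}

setMethod("show", "CorenessRegressor", function(object) {
  cat("CorenessRegressor\n")
  cat("  training windows:",
      paste(vapply(object@train, nrow, 1L), collapse = "/"),
      "per structured class\n")
  cat("  f_core: "); show(object@fCore)
  cat("  f_non:  "); show(object@fNon)
})
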