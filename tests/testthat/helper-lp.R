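# Tiny-LP fixtures and the dense-simplex oracle shared by the LP unit
# tests and the acceptance suite.

tinyAlphabet <- function(ngroups = 1L) {
  groups <- stats::setNames(rep(letters[seq_len(ngroups)], length.out = 20),
                            coreMSA:::.AA20)
  stateAlphabet("custom", groups = groups)
}

# point-mass or mixed windows over a tiny alphabet, window width 0
tinyPool <- function(stateOf, mixed = integer(0), seed = 1,
                     alpha = tinyAlphabet()) {
  ns <- nStates(alpha)
  n <- length(stateOf)
  prof <- matrix(0, n, ns)
  set.seed(seed)
  for (i in seq_len(n)) {
    if (i %in% mixed) {
      x <- rgamma(ns, 1); prof[i, ] <- x / sum(x)
    } else prof[i, stateOf[i]] <- 1
  }
  classes <- rep(c(structuredClasses(), "NNN"),
                 length.out = n)
  new("WindowSet", profiles = prof, width = 0L, alphabet = alpha,
      info = data.frame(column = seq_len(n), class = classes,
                        label = ifelse(classes %in% coreClasses(), "C", "N"),
                        coreness = as.numeric(classes %in% coreClasses())))
}

tinySets <- function(pool) {
  cls <- pool@info$class
  Tc <- lapply(structuredClasses(), function(cl) which(cls == cl))
  names(Tc) <- structuredClasses()
  new("WindowSets", pool = pool, Tc = Tc,
      Sc = lapply(Tc, function(x) x[1L]),
      bottom = which(cls == "NNN"), test = integer(0), seed = 1L,
      sizes = list())
}

# dense LP oracle: builds target/impostor/self/triangle rows from first
# principles and solves with the helper's two-phase dense simplex
oracleObjective <- function(sets, nbhd, alpha) {
  pool <- sets@pool
  prof <- pool@profiles
  ns <- ncol(prof)
  pairs <- which(upper.tri(matrix(0, ns, ns), diag = TRUE), arr.ind = TRUE)
  keep <- !(pairs[, 1] == ns & pairs[, 2] == ns)
  pu <- pairs[keep, 1]; qu <- pairs[keep, 2]
  np <- length(pu)
  coefOf <- function(V, W) {
    O <- outer(V, W)
    v <- O[cbind(pu, qu)] + O[cbind(qu, pu)]
    v[pu == qu] <- v[pu == qu] / 2
    v
  }
  cls <- structuredClasses()
  nSig <- 5 * np
  sigCol <- function(b) (match(b, cls) - 1) * np + seq_len(np)
  nBottom <- length(nbhd$bottomSamples)
  nE <- 5L
  nF <- 5L + nBottom
  nv <- nSig + nE + nF + 1L
  tauCol <- nv
  A <- NULL; b <- NULL
  addRow <- function(row, rhs) {
    A <<- rbind(A, row); b <<- c(b, rhs)
  }
  # targets (k = 1): one per structured class
  for (ci in seq_along(cls)) {
    W <- nbhd$samples[[cls[ci]]][1L]
    V <- nbhd$targets[[cls[ci]]][1, 1]
    row <- numeric(nv)
    row[sigCol(cls[ci])] <- coefOf(prof[V, ], prof[W, ])
    row[nSig + ci] <- -1
    row[tauCol] <- -1
    addRow(row, 0)
  }
  # impostors (l = 1): per structured sample, per other class; plus bottom
  for (ci in seq_along(cls)) {
    W <- nbhd$samples[[cls[ci]]][1L]
    for (bl in setdiff(cls, cls[ci])) {
      V <- nbhd$impostors[[cls[ci]]][[bl]][1, 1]
      row <- numeric(nv)
      row[sigCol(bl)] <- -coefOf(prof[V, ], prof[W, ])
      row[nSig + nE + ci] <- -1
      row[tauCol] <- 1
      addRow(row, -1)
    }
  }
  for (bi in seq_len(nBottom)) {
    W <- nbhd$bottomSamples[bi]
    for (bl in coreClasses()) {
      V <- nbhd$bottomImpostors[[bl]][bi, 1]
      row <- numeric(nv)
      row[sigCol(bl)] <- -coefOf(prof[V, ], prof[W, ])
      row[nSig + nE + 5L + bi] <- -1
      row[tauCol] <- 1
      addRow(row, -1)
    }
  }
  # self-dissimilarity and triangle rows, all state triples, every class
  pairIdx <- matrix(NA_integer_, ns, ns)
  pairIdx[cbind(pu, qu)] <- seq_len(np)
  pairIdx[cbind(qu, pu)] <- seq_len(np)
  for (ci in seq_along(cls)) {
    off <- (match(cls[ci], cls) - 1) * np
    for (p in seq_len(ns - 1)) for (q in seq_len(ns)) {
      if (p == q) next
      row <- numeric(nv)
      row[off + pairIdx[p, p]] <- row[off + pairIdx[p, p]] + 1
      row[off + pairIdx[p, q]] <- row[off + pairIdx[p, q]] - 1
      addRow(row, 0)
    }
    for (p in seq_len(ns)) for (r in seq_len(ns)) for (q in seq_len(ns)) {
      if (p >= r || q == p || q == r) next
      row <- numeric(nv)
      if (!is.na(pairIdx[p, r])) row[off + pairIdx[p, r]] <- 1
      row[off + pairIdx[p, q]] <- row[off + pairIdx[p, q]] - 1
      row[off + pairIdx[q, r]] <- row[off + pairIdx[q, r]] - 1
      addRow(row, 0)
    }
  }
  obj <- numeric(nv)
  obj[nSig + seq_len(nE)] <- alpha / 5
  obj[nSig + nE + seq_len(5L)] <- (1 - alpha) / 6
  obj[nSig + nE + 5L + seq_len(nBottom)] <- (1 - alpha) / (6 * nBottom)
  simplexLP(obj, A, b)$value
}

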