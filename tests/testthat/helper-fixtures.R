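# Shared fixtures, all built in code.

# one-hot secondary-structure confidences for an alignment: every residue
# gets probability 1 on `state` (or a per-sequence vector of states)
oneHotSS <- function(alignment, state = "H") {
  ids <- msaIDs(alignment)
  nres <- rowSums(msaMatrix(alignment) != "-")
  ss <- lapply(seq_along(ids), function(i) {
    st <- if (length(state) > 1L) state[i] else state
    conf <- matrix(0, nres[i], 3, dimnames = list(NULL, c("H", "E", "C")))
    conf[, st] <- 1
    conf
  })
  names(ss) <- ids
  ss
}

# per-residue states given explicitly as strings over H/E/C (gaps skipped)
ssFromStrings <- function(alignment, stateStrings) {
  ids <- msaIDs(alignment)
  ss <- lapply(seq_along(ids), function(i) {
    st <- strsplit(stateStrings[i], "")[[1]]
    conf <- matrix(0, length(st), 3, dimnames = list(NULL, c("H", "E", "C")))
    conf[cbind(seq_along(st), match(st, c("H", "E", "C")))] <- 1
    conf
  })
  names(ss) <- ids
  ss
}

# small labeled window pool drawn from a synthetic suite; memoized so the
# expensive pieces are built once per test run
.fixtureEnv <- new.env(parent = emptyenv())

smallSuite <- function() {
  if (!is.null(.fixtureEnv$suite)) return(.fixtureEnv$suite)
  cfg <- suiteConfig(nBenchmarks = 6, k = 8, m = 60,
                     accuracyLevels = c(0.2, 0.5, 0.8, 1.0), seed = 11)
  bms <- lapply(1:6, function(i) generateBenchmark(cfg, seed = 100 + i))
  names(bms) <- paste0("b", 1:6)
  alphabet <- stateAlphabet("reduced5")
  pools <- lapply(names(bms), function(id)
    benchmarkWindows(bms[[id]], w = 1, alphabet = alphabet, id = id))
  pool <- bindWindows(pools)
  fold <- match(pool@info$benchmark, names(bms))
  sets <- assembleWindowSets(pool, fold, testFolds = c(5L, 6L),
                             sizeT = 30, sizeS = 50, sizeTest = 300,
                             sizeBottom = 30, seed = 3)
  .fixtureEnv$suite <- list(config = cfg, benchmarks = bms, pool = pool,
                            fold = fold, sets = sets, alphabet = alphabet)
  .fixtureEnv$suite
}

# a tiny trained model + regressor on the small suite (one LP solve)
smallModel <- function() {
  if (!is.null(.fixtureEnv$model)) return(.fixtureEnv$model)
  fx <- smallSuite()
  sol <- trainDistanceModel(fx$sets, mode = "random", k = 2, l = 10,
                            alpha = 0.5, seed = 5, triangles = "full",
                            impostors = "all")
  reg <- buildCorenessRegressor(sol$model, fx$sets, ell = 20)
  .fixtureEnv$model <- list(sol = sol, regressor = reg)
  .fixtureEnv$model
}

# random point-mass window over an alphabet (flattened), for metric tests
randomPointMassWindow <- function(alphabet, w = 1L) {
  ns <- nStates(alphabet)
  P <- 2L * w + 1L
  v <- numeric(P * ns)
  for (i in seq_len(P)) v[(i - 1L) * ns + sample.int(ns, 1L)] <- 1
  v
}

# random dense window: independent random distribution at each position
randomWindow <- function(alphabet, w = 1L) {
  ns <- nStates(alphabet)
  P <- 2L * w + 1L
  v <- numeric(P * ns)
  for (i in seq_len(P)) {
    x <- rgamma(ns, 1)
    v[(i - 1L) * ns + seq_len(ns)] <- x / sum(x)
  }
  v
}

# a DistanceModel whose tables are guaranteed metrics: distances between
# random points on the line (plus zero diagonal), per class and position
randomMetricModel <- function(alphabet, w = 1L) {
  ns <- nStates(alphabet)
  P <- 2L * w + 1L
  sigma <- lapply(structuredClasses(), function(cl) {
    a <- array(0, dim = c(ns, ns, P))
    for (i in seq_len(P)) {
      x <- runif(ns, 0, 5)
      a[, , i] <- abs(outer(x, x, `-`))
      a[ns, ns, i] <- 0
    }
    a
  })
  names(sigma) <- structuredClasses()
  new("DistanceModel", sigma = sigma, tau = runif(1, 0, 2), width = as.integer(w),
      alphabet = alphabet)
}

# Full-scale training fixture: a 12-benchmark suite with difficulty-spread
# candidates, a distance model learned with random neighborhoods on the
# 3-group reduced alphabet (|S| = 200, k = 2, l = 20), and the fitted
# regressor. Built once per test run.
acceptanceFixture <- function() {
  if (!is.null(.fixtureEnv$acc)) return(.fixtureEnv$acc)
  cfg <- suiteConfig(nBenchmarks = 12, k = 8, m = 60, seed = 42)
  alphabet <- stateAlphabet("reduced3")
  diffs <- coreMSA:::.suiteDifficulties(12)
  bms <- lapply(1:12, function(i)
    generateBenchmark(cfg, seed = 1000 + i, difficulty = diffs[i]))
  names(bms) <- sprintf("b%02d", 1:12)
  pools <- lapply(names(bms), function(id)
    benchmarkWindows(bms[[id]], w = 1, alphabet = alphabet, id = id))
  pool <- bindWindows(pools)
  benchFold <- assignFolds(vapply(bms, function(b) unname(b$accuracy[1]),
                                  numeric(1)), nFolds = 4, seed = 42)
  names(benchFold) <- names(bms)
  fold <- benchFold[pool@info$benchmark]
  sets <- assembleWindowSets(pool, fold, testFolds = 4L, sizeT = 300,
                             sizeS = 200, sizeTest = 1000, sizeBottom = 200,
                             seed = 7)
  sol <- trainDistanceModel(sets, mode = "random", k = 2, l = 20,
                            alpha = 0.5, seed = 7, triangles = "full",
                            impostors = "all")
  reg <- buildCorenessRegressor(sol$model, sets, ell = 20)
  .fixtureEnv$acc <- list(config = cfg, benchmarks = bms, pool = pool,
                          fold = fold, benchFold = benchFold, sets = sets,
                          sol = sol, regressor = reg, alphabet = alphabet)
  .fixtureEnv$acc
}
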