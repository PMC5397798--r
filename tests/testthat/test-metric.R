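test_that("window distance is the bilinear form over positional tables", {
  alpha <- stateAlphabet("reduced5")
  ns <- nStates(alpha)
  model <- randomMetricModel(alpha, w = 1)
  # identical point masses at zero-diagonal states are at distance zero
  set.seed(1)
  V <- randomPointMassWindow(alpha)
  expect_equal(windowDistance(model, "CCC", V, V), 0)
  # point masses on p and q at all 3 positions sum the positional scores
  p <- 2L; q <- 5L
  V <- numeric(3 * ns); W <- numeric(3 * ns)
  for (i in 0:2) { V[i * ns + p] <- 1; W[i * ns + q] <- 1 }
  sig <- model@sigma[["CCN"]]
  expect_equal(windowDistance(model, "CCN", V, W),
               sig[p, q, 1] + sig[p, q, 2] + sig[p, q, 3])
  # half-mixed center: d = 0.5 * sigma(p,q) when flanks match at score 0
  V2 <- W2 <- numeric(3 * ns)
  V2[c(1, 2 * ns + 1)] <- 1; W2[c(1, 2 * ns + 1)] <- 1   # identical flanks
  V2[ns + p] <- 0.5; V2[ns + q] <- 0.5
  W2[ns + p] <- 1
  expect_equal(windowDistance(model, "CCC", V2, W2),
               0.5 * model@sigma[["CCC"]][p, p, 2] +
                 0.5 * model@sigma[["CCC"]][p, q, 2])
  # symmetry
  set.seed(2)
  A <- randomWindow(alpha); B <- randomWindow(alpha)
  expect_equal(windowDistance(model, "NNC", A, B),
               windowDistance(model, "NNC", B, A), tolerance = 1e-12)
  expect_error(windowDistance(model, "CCC", A[-1], B), "width mismatch")
})

test_that("the default bootstrap distance mixes residue and structure terms", {
  alpha <- stateAlphabet("full")
  dm <- defaultDistanceModel(alpha, w = 1, gammaMix = 0.5)
  ns <- nStates(alpha)
  mkwin <- function(state) {
    v <- numeric(3 * ns)
    for (i in 0:2) v[i * ns + state] <- 1
    v
  }
  iAH <- match("AH", alphabetStates(alpha))
  iAE <- match("AE", alphabetStates(alpha))
  # identical windows of identical states: distance 0
  expect_equal(windowDistance(dm, "CCC", mkwin(iAH), mkwin(iAH)), 0)
  # same residue, different structure, gammaMix 0.5: 0.5 * sum(weights) = 0.5
  expect_equal(windowDistance(dm, "CCC", mkwin(iAH), mkwin(iAE)), 0.5)
  # symmetry under argument swap
  set.seed(3)
  A <- randomWindow(alpha); B <- randomWindow(alpha)
  expect_equal(windowDistance(dm, "CCC", A, B),
               windowDistance(dm, "CCC", B, A), tolerance = 1e-12)
  # gap vs non-gap is maximal: weights sum to 1
  gap <- numeric(3 * ns); gap[ns * (1:3)] <- 1
  expect_equal(windowDistance(dm, "CCC", gap, mkwin(iAH)), 1)
  expect_equal(windowDistance(dm, "CCC", gap, gap), 0)
})

test_that("triangle verification reports score- and window-level violations", {
  alpha <- stateAlphabet("reduced5")
  model <- randomMetricModel(alpha)
  rep <- verifyTriangle(model, nTriples = 200, seed = 4)
  expect_true(rep$ok)
  expect_lte(rep$sigmaMaxViolation, 1e-9)
  expect_lte(rep$windowMaxViolation, rep$sigmaMaxViolation + 1e-9)
  # hand-built violation: sigma(p,r)=3 with sigma(p,q)=sigma(q,r)=1
  bad <- model
  ns <- nStates(alpha)
  M <- matrix(1, ns, ns); diag(M) <- 0
  M[1, 3] <- M[3, 1] <- 3
  M[ns, ns] <- 0
  bad@sigma[["CCC"]][, , 2] <- M
  rep2 <- verifyTriangle(bad, nTriples = 0)
  expect_equal(rep2$sigmaMaxViolation, 1, tolerance = 1e-12)
  expect_false(rep2$ok)
})

test_that("window-level triangle holds for any feasible score tables", {
  # Theorem-style property: random metric tables, random dense windows
  set.seed(5)
  alpha <- stateAlphabet("reduced5")
  for (rep in 1:5) {
    model <- randomMetricModel(alpha)
    for (t in 1:40) {
      cl <- sample(structuredClasses(), 1)
      U <- randomWindow(alpha); V <- randomWindow(alpha)
      W <- randomWindow(alpha)
      expect_lte(windowDistance(model, cl, U, W),
                 windowDistance(model, cl, U, V) +
                   windowDistance(model, cl, V, W) + 1e-9)
    }
  }
})

test_that("vp-tree queries equal brute-force scans including ties", {
  set.seed(6)
  alpha <- stateAlphabet("reduced5")
  model <- randomMetricModel(alpha)
  # include duplicated rows so distance ties are exercised
  Tc <- do.call(rbind, c(lapply(1:60, function(i) randomWindow(alpha)),
                         lapply(1:10, function(i) randomPointMassWindow(alpha))))
  Tc <- rbind(Tc, Tc[1:15, ])
  idx <- buildNNIndex(Tc, model, "CCN")
  expect_false(idx@brute)
  for (qn in 1:25) {
    W <- if (qn %% 3) randomWindow(alpha) else Tc[sample(nrow(Tc), 1), ]
    D <- windowCrossDist(model, "CCN", matrix(W, 1), Tc)[1, ]
    for (i in c(1L, 3L)) {
      got <- nnQuery(idx, W, i)
      want <- order(round(D * 1e9), seq_along(D))[1:i]
      expect_identical(got$index, want)
      expect_equal(got$distance, D[want], tolerance = 1e-9)
    }
  }
})

test_that("a singleton index always returns its element", {
  alpha <- stateAlphabet("reduced5")
  model <- randomMetricModel(alpha)
  set.seed(8)
  Tc <- matrix(randomWindow(alpha), 1)
  idx <- buildNNIndex(Tc, model, "CCC")
  r <- nnQuery(idx, randomWindow(alpha), 1)
  expect_equal(r$index, 1L)
})

test_that("triangle-violating models fall back to exact brute force", {
  alpha <- stateAlphabet("reduced5")
  model <- randomMetricModel(alpha)
  ns <- nStates(alpha)
  M <- matrix(1, ns, ns); diag(M) <- 0; M[1, 3] <- M[3, 1] <- 5
  M[ns, ns] <- 0
  model@sigma[["CCC"]][, , 1] <- M
  set.seed(9)
  Tc <- do.call(rbind, lapply(1:30, function(i) randomWindow(alpha)))
  expect_warning(idx <- buildNNIndex(Tc, model, "CCC"), "triangle")
  expect_true(idx@brute)
  W <- randomWindow(alpha)
  D <- windowCrossDist(model, "CCC", matrix(W, 1), Tc)[1, ]
  expect_identical(nnQuery(idx, W, 1)$index, which.min(D))
})

test_that("nearest structured class takes the global minimum with fixed ties", {
  set.seed(10)
  alpha <- stateAlphabet("reduced5")
  model <- randomMetricModel(alpha)
  sets <- lapply(structuredClasses(), function(cl)
    do.call(rbind, lapply(1:40, function(i) randomWindow(alpha))))
  names(sets) <- structuredClasses()
  indices <- lapply(structuredClasses(), function(cl)
    buildNNIndex(sets[[cl]], model, cl))
  names(indices) <- structuredClasses()
  for (qn in 1:10) {
    W <- randomWindow(alpha)
    got <- nearestStructured(indices, W)
    mins <- vapply(structuredClasses(), function(cl)
      min(windowCrossDist(model, cl, matrix(W, 1), sets[[cl]])), numeric(1))
    expect_equal(got$distance, min(mins), tolerance = 1e-12)
    expect_equal(got$class,
                 structuredClasses()[which.min(mins)])
  }
  # an exact point-mass training window comes back at distance zero (the
  # score diagonals of this metric model are zero)
  W <- randomPointMassWindow(alpha)
  sets0 <- sets
  sets0[["NCC"]][7, ] <- W
  idx0 <- lapply(structuredClasses(), function(cl)
    buildNNIndex(sets0[[cl]], model, cl))
  names(idx0) <- structuredClasses()
  got <- nearestStructured(idx0, W)
  expect_lte(got$distance, 1e-9)
  # deterministic tie-break: duplicate window in two classes -> earlier class
  sets2 <- sets
  sets2[["CCN"]][1, ] <- W
  sets2[["NNC"]][1, ] <- W
  idx2 <- lapply(structuredClasses(), function(cl)
    buildNNIndex(sets2[[cl]], model, cl))
  names(idx2) <- structuredClasses()
  got2 <- nearestStructured(idx2, W)
  expect_equal(got2$class, "CCN")
  expect_error(nearestStructured(idx2[1:3], W), "per structured class")
})

test_that("batch nearest-structured search agrees with per-query indices", {
  fx <- smallSuite()
  model <- randomMetricModel(fx$alphabet)
  train <- lapply(fx$sets@Tc, function(i) fx$pool@profiles[i, , drop = FALSE])
  indices <- lapply(structuredClasses(), function(cl)
    buildNNIndex(train[[cl]], model, cl))
  names(indices) <- structuredClasses()
  q <- fx$pool@profiles[fx$sets@test[1:20], , drop = FALSE]
  batch <- coreMSA:::.nearestStructuredBatch(model, train, q)
  for (i in 1:20) {
    single <- nearestStructured(indices, q[i, ])
    expect_equal(batch$distance[i], single$distance, tolerance = 1e-12)
    expect_equal(as.character(batch$class[i]), single$class)
  }
})
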