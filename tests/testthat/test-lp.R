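# Tiny LP instances over a one-group alphabet (4 states, window width 0);
# fixtures and the dense-simplex oracle live in helper-lp.R.

test_that("the LP optimum matches an independent dense-simplex oracle", {
  skip_if(Sys.which("python") == "" && Sys.getenv("COREMSA_PYTHON") == "")
  set.seed(31)
  for (rep in 1:4) {
    stateOf <- sample(1:3, 12, replace = TRUE)
    pool <- tinyPool(stateOf, mixed = if (rep > 2) c(2L, 7L), seed = rep)
    sets <- tinySets(pool)
    nbhd <- buildNeighborhoods(sets, "random", k = 1, l = 1, seed = rep)
    for (alpha in c(0.3, 0.7)) {
      lp <- buildDistanceLP(sets, nbhd, alpha = alpha, triangles = "full",
                            impostors = "all")
      sol <- solveDistanceLP(lp)
      expect_equal(sol$objective, oracleObjective(sets, nbhd, alpha),
                   tolerance = 1e-3)
      chk <- checkLPSolution(lp, sol, tol = 1e-5)
      expect_true(chk$ok)
    }
  }
})

test_that("a separable point-mass instance reaches objective zero", {
  # six classes on six distinct states (2-group alphabet): every target
  # pair coincides and every impostor pair differs, so zero error is
  # feasible (tau = 0, same-state scores 0, cross-state scores >= 1) and
  # the LP finds it
  stateOf <- rep(1:6, 2)    # class i on state i, two windows each
  pool <- tinyPool(stateOf, alpha = tinyAlphabet(2L))
  sets <- tinySets(pool)
  nbhd <- buildNeighborhoods(sets, "random", k = 1, l = 1, seed = 2)
  lp <- buildDistanceLP(sets, nbhd, alpha = 0.5, triangles = "full",
                        impostors = "all")
  sol <- solveDistanceLP(lp)
  expect_equal(sol$objective, 0, tolerance = 1e-6)
  expect_true(checkLPSolution(lp, sol, 1e-5)$ok)
  expect_gte(modelTau(sol$model), 0)
})

test_that("the all-zero model bounds the optimum by (1 - alpha)", {
  pool <- tinyPool(sample(1:3, 12, replace = TRUE))
  sets <- tinySets(pool)
  nbhd <- buildNeighborhoods(sets, "random", k = 1, l = 1, seed = 3)
  for (alpha in c(0.2, 0.8)) {
    lp <- buildDistanceLP(sets, nbhd, alpha = alpha, triangles = "full",
                          impostors = "all")
    sol <- solveDistanceLP(lp)
    expect_gte(sol$objective, -1e-9)
    expect_lte(sol$objective, (1 - alpha) + 1e-6)
  }
})

test_that("cutting-plane generation reaches the enumerated optimum", {
  set.seed(33)
  pool <- tinyPool(sample(1:3, 12, replace = TRUE), mixed = c(1L, 5L, 9L))
  sets <- tinySets(pool)
  nbhd <- buildNeighborhoods(sets, "random", k = 1, l = 1, seed = 4)
  full <- solveDistanceLP(buildDistanceLP(sets, nbhd, alpha = 0.5,
                                          triangles = "full",
                                          impostors = "all"))
  lazy <- solveDistanceLP(buildDistanceLP(sets, nbhd, alpha = 0.5,
                                          triangles = "none",
                                          impostors = "lazy"))
  expect_equal(lazy$objective, full$objective, tolerance = 1e-6)
  expect_true(lazy$info$certified)
  expect_lte(verifyTriangle(lazy$model, nTriples = 0)$sigmaMaxViolation,
             1e-6)
})

test_that("neighborhood construction is seeded and class-consistent", {
  fx <- smallSuite()
  n1 <- buildNeighborhoods(fx$sets, "random", k = 2, l = 5, seed = 9)
  n2 <- buildNeighborhoods(fx$sets, "random", k = 2, l = 5, seed = 9)
  expect_identical(n1$targets, n2$targets)
  expect_identical(n1$impostors, n2$impostors)
  cls <- fx$pool@info$class
  for (cl in structuredClasses()) {
    expect_true(all(cls[n1$targets[[cl]]] == cl))
    for (bl in setdiff(structuredClasses(), cl)) {
      expect_true(all(cls[n1$impostors[[cl]][[bl]]] == bl))
      expect_false(any(n1$impostors[[cl]][[bl]] %in% fx$sets@Tc[[cl]]))
    }
    # a window is never its own target
    S <- n1$samples[[cl]]
    for (i in seq_along(S))
      expect_false(S[i] %in% n1$targets[[cl]][i, ])
  }
  expect_error(buildNeighborhoods(fx$sets, "random", k = 100, l = 5),
               "k\\+1")
})

test_that("default-distance neighborhoods equal a brute-force k-NN scan", {
  fx <- smallSuite()
  nb <- buildNeighborhoods(fx$sets, "default", k = 2, l = 3, seed = 1)
  dm <- defaultDistanceModel(fx$alphabet, 1)
  prof <- fx$pool@profiles
  for (cl in c("CCC", "NNC")) {
    S <- nb$samples[[cl]]; Tc <- fx$sets@Tc[[cl]]
    for (i in seq_along(S)[1:5]) {
      d <- windowCrossDist(dm, cl, prof[S[i], , drop = FALSE],
                           prof[Tc, , drop = FALSE])[1, ]
      d[which(Tc == S[i])] <- Inf
      want <- Tc[order(d, seq_along(d))[1:2]]
      expect_identical(nb$targets[[cl]][i, ], want)
    }
  }
})

test_that("solved LPs satisfy the error-variable identities", {
  md <- smallModel()
  chk <- md$sol$check
  expect_true(chk$ok)
  expect_lte(chk$eIdentity, 1e-5)
  expect_lte(chk$fIdentity, 1e-5)
  expect_lte(chk$triangle, 1e-6)
})

test_that("iterated training rebuilds neighborhoods under the new model", {
  fx <- smallSuite()
  sets <- assembleWindowSets(fx$pool, fx$fold, testFolds = c(5L, 6L),
                             sizeT = 12, sizeS = 15, sizeTest = 40,
                             sizeBottom = 8, seed = 23)
  it <- iterateTraining(sets, nIters = 2, startMode = "random",
                        k = 1, l = 2, alpha = 0.5, seed = 17, ell = 10,
                        triangles = "full")
  expect_length(it$models, 2L)
  expect_true(all(is.finite(it$auc$train)))
  # iteration-2 neighborhoods are the model-mode neighborhoods under the
  # iteration-1 model
  nb2 <- buildNeighborhoods(sets, "model", k = 1, l = 2, seed = 19,
                            model = it$models[[1]])
  nbAlt <- buildNeighborhoods(sets, "model", k = 1, l = 2, seed = 19,
                              model = it$models[[1]])
  expect_identical(nb2$targets, nbAlt$targets)
})
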