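test_that("column profiles follow the state-confidence definition", {
  alpha <- stateAlphabet("full")
  # k=2, column (A, '-'), p1 one-hot helix
  p <- columnProfile(c("A", "-"), matrix(c(1, 0, 0), 1), alpha)
  expect_equal(unname(p["AH"]), 0.5)
  expect_equal(unname(p["--"]), 0.5)
  expect_equal(sum(p), 1)
  expect_equal(sum(p != 0), 2L)
  # k=2, both A with a split confidence
  p <- columnProfile(c("A", "A"), rbind(c(.6, .1, .3), c(.6, .1, .3)), alpha)
  expect_equal(unname(p[c("AH", "AE", "AC")]), c(.6, .1, .3))
  # k=3 mixed residues
  p <- columnProfile(c("A", "C", "-"), rbind(c(1, 0, 0), c(0, 1, 0)), alpha)
  expect_equal(unname(p[c("AH", "CE", "--")]), rep(1 / 3, 3))
  expect_error(columnProfile(c("A", "A"), matrix(c(1, 0, 0), 1), alpha),
               "one confidence triple")
})

test_that("ambiguity codes spread mass uniformly over their expansion", {
  alpha <- stateAlphabet("full")
  p <- columnProfile(c("B", "B"), rbind(c(1, 0, 0), c(1, 0, 0)), alpha)
  expect_equal(unname(p["DH"]), 0.5)
  expect_equal(unname(p["NH"]), 0.5)
  p <- columnProfile(c("X", "-"), matrix(c(0, 0, 1), 1), alpha)
  expect_equal(unname(p["AC"]), 0.5 / 20)
  expect_equal(sum(p), 1)
})

test_that("profile matrices sum to one per column on random alignments", {
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(2:6, 1); m <- sample(2:15, 1)
    rows <- vapply(seq_len(k), function(i)
      paste(sample(c("A", "C", "G", "W", "-"), m, replace = TRUE),
            collapse = ""), "")
    rows[1] <- gsub("-", "A", rows[1])   # keep at least one residue per seq
    aln <- proteinAlignment(rows)
    states <- vapply(seq_len(k), function(i)
      paste(sample(c("H", "E", "C"),
                   sum(strsplit(rows[i], "")[[1]] != "-"),
                   replace = TRUE), collapse = ""), "")
    ss <- ssFromStrings(aln, states)
    alpha <- if (rep %% 2) stateAlphabet("full") else stateAlphabet("reduced5")
    P <- profileMatrix(aln, ss, alpha)
    expect_equal(unname(colSums(P)), rep(1, m), tolerance = 1e-9)
    # gap row matches gap frequency
    expect_equal(unname(P[nStates(alpha), ]),
                 unname(colMeans(msaMatrix(aln) == "-")))
  }
})

test_that("windows are edge-padded with pure gap-state profiles", {
  aln <- proteinAlignment(c("A", "C"))
  ss <- oneHotSS(aln)
  alpha <- stateAlphabet("full")
  ws <- extractWindows(aln, ss, w = 1, alphabet = alpha)
  ns <- nStates(alpha)
  expect_equal(nrow(ws@profiles), 1L)
  left <- ws@profiles[1, 1:ns]
  expect_equal(unname(left[ns]), 1)      # pure gap state
  expect_equal(sum(left), 1)
  # center slice equals the column profile, for every column
  aln5 <- proteinAlignment(c("ACDEF", "AC-EF"))
  ss5 <- oneHotSS(aln5, "E")
  ws5 <- extractWindows(aln5, ss5, w = 1, alphabet = alpha)
  expect_equal(nrow(ws5@profiles), 5L)
  P <- profileMatrix(aln5, ss5, alpha)
  for (j in 1:5)
    expect_equal(unname(ws5@profiles[j, ns + 1:ns]), unname(P[, j]))
  # window 2 covers columns 1,2,3
  expect_equal(unname(ws5@profiles[2, 1:ns]), unname(P[, 1]))
  expect_equal(unname(ws5@profiles[2, 2 * ns + 1:ns]), unname(P[, 3]))
})

test_that("window classes follow the center-run vocabulary with exclusions", {
  expect_equal(windowClass(c("C", "C", "N")), "CCN")
  expect_equal(windowClass(c("N", "C", "N")), "excluded")
  expect_equal(windowClass(c("C", "N", "C")), "excluded")
  expect_equal(windowClass(c("N", "N", "N")), "NNN")
  expect_equal(windowClass(c("C", "C", "C")), "CCC")
  # wider windows classify by the center column and its immediate flanks
  expect_equal(windowClass(c("N", "C", "C", "N", "N")), "CCN")
  expect_error(windowClass(c("C", "N")))
})

test_that("per-column classes match a direct scan of the label string", {
  set.seed(3)
  for (rep in 1:25) {
    labels <- sample(c("C", "N"), 12, replace = TRUE)
    cls <- coreMSA:::.columnClasses(labels)
    padded <- c("N", labels, "N")
    for (j in seq_along(labels)) {
      expect_equal(cls[j], windowClass(padded[j:(j + 2)]))
    }
  }
})

test_that("profiles are invariant under permuting sequences", {
  fx <- smallSuite()
  bm <- fx$benchmarks[[1]]
  aln <- bm$computed[[2]]
  perm <- sample(nSequences(aln))
  aln2 <- proteinAlignment(apply(msaMatrix(aln)[perm, ], 1, paste,
                                 collapse = ""), ids = msaIDs(aln)[perm])
  P1 <- profileMatrix(aln, bm$ss, fx$alphabet)
  P2 <- profileMatrix(aln2, bm$ss, fx$alphabet)
  expect_equal(P1, P2, tolerance = 1e-12)
})

test_that("gap-free one-hot columns give point masses iff monomorphic", {
  aln <- proteinAlignment(c("AAC", "AGC"))
  ss <- oneHotSS(aln, "H")
  P <- profileMatrix(aln, ss, stateAlphabet("full"))
  expect_equal(max(P[, 1]), 1)        # A/A same state: point mass
  expect_lt(max(P[, 2]), 1)           # A/G polymorphic
  expect_equal(max(P[, 3]), 1)
})

test_that("window set assembly is seeded, sized, and class-pure", {
  fx <- smallSuite()
  s1 <- assembleWindowSets(fx$pool, fx$fold, testFolds = c(5L, 6L),
                           sizeT = 10, sizeS = 10, sizeTest = 40,
                           sizeBottom = 10, seed = 7)
  s2 <- assembleWindowSets(fx$pool, fx$fold, testFolds = c(5L, 6L),
                           sizeT = 10, sizeS = 10, sizeTest = 40,
                           sizeBottom = 10, seed = 7)
  expect_identical(s1@Tc, s2@Tc)
  expect_identical(s1@Sc, s2@Sc)
  expect_identical(s1@test, s2@test)
  for (cl in structuredClasses()) {
    expect_true(all(fx$pool@info$class[s1@Tc[[cl]]] == cl))
    expect_true(all(s1@Sc[[cl]] %in% s1@Tc[[cl]]))
  }
  expect_true(all(fx$pool@info$class[s1@bottom] == "NNN"))
  # test windows come only from the held-out folds
  expect_true(all(fx$fold[s1@test] %in% c(5L, 6L)))
  expect_true(all(!fx$fold[unlist(s1@Tc)] %in% c(5L, 6L)))
  # over-requesting reports availability
  expect_error(assembleWindowSets(fx$pool, fx$fold, testFolds = c(5L, 6L),
                                  sizeT
               = 10000, sizeS = 10, sizeTest = 40, seed = 1),
               "available")
})

test_that("fold assignment balances difficulty bins round-robin", {
  difficulty <- c(runif(24, 0, 0.3), runif(24, 0.7, 1))
  folds <- assignFolds(difficulty, nFolds = 12, seed = 2)
  expect_true(all(folds %in% 1:12))
  # each difficulty half spreads over all folds
  expect_equal(sort(unique(folds[1:24])), 1:12)
  expect_equal(sort(unique(folds[25:48])), 1:12)
})
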