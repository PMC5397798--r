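test_that("sequence statistics match hand-computed LCS ratios", {
  s <- sequenceStats(c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(s$lmin, 10); expect_equal(s$lavg, 10); expect_equal(s$lmax, 10)
  expect_equal(s$pmin, 1); expect_equal(s$pmax, 1)
  expect_equal(s$qmin, 1); expect_equal(s$rmin, 0); expect_equal(s$ravg, 0)
  # "ACGT" vs "ACT": LCS = 3
  s <- sequenceStats(c("ACGT", "ACT"))
  expect_equal(s$pmin, 1)
  expect_equal(s$pmax, 0.75)
  expect_equal(s$pavg, 3 / 3.5)
  expect_equal(s$rmin, 1 / 3)
  expect_equal(s$qmin, 3 / 4)
  # order invariance
  s2 <- sequenceStats(c("ACT", "ACGT"))
  expect_equal(s, s2)
  expect_error(sequenceStats(c("", "ACGT")), "empty")
})

test_that("LCS via weighted edit distance equals a direct dynamic program", {
  lcsDP <- function(a, b) {
    a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
    D <- matrix(0L, length(a) + 1L, length(b) + 1L)
    for (i in seq_along(a)) for (j in seq_along(b))
      D[i + 1, j + 1] <- if (a[i] == b[j]) D[i, j] + 1L else
        max(D[i, j + 1], D[i + 1, j])
    D[length(a) + 1L, length(b) + 1L]
  }
  set.seed(21)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "W"), sample(3:12, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "W"), sample(3:12, 1), TRUE),
               collapse = "")
    d <- utils::adist(a, b, costs = list(ins = 1, del = 1, sub = 2))[1, 1]
    expect_equal((nchar(a) + nchar(b) - d) / 2, lcsDP(a, b))
  }
})

test_that("the shipped normalizer reproduces hand arithmetic", {
  s <- sequenceStats(c("ACDEFGHIKL", "ACDEFGHIKL"))
  # 1.020*10 + 0.151*10 + 0.035*10 + 0 + 0
  expect_equal(normalizerValue(defaultNormalizer(), s), 12.06,
               tolerance = 1e-12)
  # all active default terms are degree 1 in length: doubling scales by 2
  s2 <- sequenceStats(c(strrep("ACDEFGHIKL", 2), strrep("ACDEFGHIKL", 2)))
  expect_equal(normalizerValue(defaultNormalizer(), s2), 2 * 12.06,
               tolerance = 1e-12)
  zero <- new("NormalizerModel",
              coefficients = c("lmin" = 0))
  expect_equal(normalizerValue(zero, s), 0)
})

test_that("the candidate term set has 72 members over distinct ratio groups", {
  terms <- coreMSA:::.normalizerTerms()
  expect_length(terms, 72L)
  expect_false(anyDuplicated(terms) > 0)
  # no term multiplies two ratios of the same group
  for (tm in terms) {
    fac <- strsplit(tm, "*", fixed = TRUE)[[1]]
    grp <- substr(fac, 1, 1)
    expect_false(anyDuplicated(grp[-1]) > 0)
  }
})

test_that("normalizer fitting recovers a planted combination exactly", {
  set.seed(22)
  statsList <- lapply(1:12, function(i) {
    a <- paste(sample(c("A","C","D","E","F","G"), sample(20:60, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A","C","D","E","F","G"), sample(20:60, 1), TRUE),
               collapse = "")
    sequenceStats(c(a, b))
  })
  y <- vapply(statsList, function(s) 1.5 * s$lmin * s$pmax * s$qmin,
              numeric(1))
  fit <- fitNormalizer(statsList, y)
  pred <- vapply(statsList, function(s) normalizerValue(fit, s), numeric(1))
  expect_equal(pred, y, tolerance = 1e-6)
  # fitted residual no worse than the shipped default's on the same data
  resid <- function(model) sum(abs(vapply(statsList, function(s)
    normalizerValue(model, s), numeric(1)) - y))
  expect_lte(resid(fit), resid(defaultNormalizer()) + 1e-8)
})

test_that("gap features count runs and entries", {
  aln <- proteinAlignment(c("AA--", "A-AA"))
  g <- featureGaps(aln)
  expect_equal(unname(g["F_GE"]), 3 / 8)
  expect_equal(unname(g["F_GO"]), 2 / 3)
  expect_equal(unname(featureGaps(proteinAlignment(c("ACD", "ACD")))),
               c(0, 0))
  allgap <- proteinAlignment(c("----", "ACDE"))
  g <- featureGaps(allgap)
  expect_equal(unname(g["F_GO"]), 1 / 4)   # one run start, four gaps
})

test_that("identity-family features and their augmentations behave", {
  aln <- proteinAlignment(c("AC", "AC"))
  ss <- oneHotSS(aln, "H")
  f <- featureIdentityFamily(aln, ss, weights = c(1, 1))
  expect_equal(unname(f["F_SI"]), 1)
  expect_equal(unname(f["F_AI"]), 1)
  expect_equal(unname(f["F_SI_aug"]), unname(f["F_SI"]))
  expect_equal(unname(f["F_AS_aug"]), unname(f["F_AS"]))
  # col1 pair matches SS, col2 does not; weights (1, 0) -> augmented SI = 1
  aln2 <- proteinAlignment(c("AC", "AC"))
  ss2 <- ssFromStrings(aln2, c("HH", "HE"))
  f2 <- featureIdentityFamily(aln2, ss2, weights = c(1, 0))
  expect_equal(unname(f2["F_SI"]), 0.5)
  expect_equal(unname(f2["F_SI_aug"]), 1)
  # amino-acid identity groups equivalent residues (L and V share a class)
  aln3 <- proteinAlignment(c("LK", "VR"))
  f3 <- featureIdentityFamily(aln3, oneHotSS(aln3, "C"))
  expect_equal(unname(f3["F_AI"]), 1)
})

test_that("secondary-structure agreement follows confidence dot products", {
  aln <- proteinAlignment(c("ACDEF", "ACDEF"))
  expect_equal(featureSSAgreement(aln, oneHotSS(aln, "H")), 1)
  expect_equal(featureSSAgreement(aln, oneHotSS(aln, c("H", "E"))), 0)
  ids <- msaIDs(aln)
  ss <- lapply(ids, function(i)
    matrix(1 / 3, 5, 3, dimnames = list(NULL, c("H", "E", "C"))))
  names(ss) <- ids
  expect_equal(featureSSAgreement(aln, ss), 1 / 3, tolerance = 1e-12)
})

test_that("blockiness finds optimal packings (vs exhaustive enumeration)", {
  # uniform helix, no gaps: one block covers everything
  aln <- proteinAlignment(c("ACDE", "ACDE", "ACDE"))
  expect_equal(unname(featureBlockiness(aln, oneHotSS(aln, "H"))["F_BL"]), 1)
  # alternating helix/strand columns: width-1 blocks still cover all pairs,
  # but a minimum width of 2 forbids them
  ss <- ssFromStrings(aln, rep("HEHE", 3))
  expect_equal(unname(featureBlockiness(aln, ss)["F_BL"]), 1)
  expect_equal(unname(featureBlockiness(aln, ss, minWidth = 2)["F_BL"]), 0)

  # exhaustive oracle on small random alignments
  bruteBlockiness <- function(aln, ss, w) {
    A <- coreMSA:::.ssArgmaxMatrix(aln, ss)
    m <- ncol(A)
    score <- function(i, j, s) {
      elig <- rep(TRUE, nrow(A))
      for (t in i:j) elig <- elig & !is.na(A[, t]) & A[, t] == s
      r <- sum(elig)
      if (r < 2) 0 else choose(r, 2) * sum(w[i:j])
    }
    best <- 0
    recurse <- function(col, acc) {
      if (col > m) { best <<- max(best, acc); return(invisible()) }
      recurse(col + 1, acc)                       # leave col uncovered
      for (j in col:m) for (s in c("H", "E", "C"))
        recurse(j + 1, acc + score(col, j, s))
    }
    recurse(1, 0)
    den <- sum(vapply(seq_len(m), function(j)
      choose(sum(!is.na(A[, j])), 2), numeric(1)) * w)
    if (den <= 0) 0 else best / den
  }
  set.seed(23)
  for (rep in 1:8) {
    k <- sample(2:4, 1); m <- sample(3:6, 1)
    rows <- vapply(seq_len(k), function(i)
      paste(sample(c("A", "C", "-"), m, replace = TRUE, prob = c(.4, .4, .2)),
            collapse = ""), "")
    rows[1] <- gsub("-", "A", rows[1])
    rows[2] <- gsub("-", "C", rows[2])
    aln <- proteinAlignment(rows)
    states <- vapply(seq_len(k), function(i)
      paste(sample(c("H", "E", "C"), sum(strsplit(rows[i], "")[[1]] != "-"),
                   TRUE), collapse = ""), "")
    ss <- ssFromStrings(aln, states)
    w <- if (rep %% 2) rep(1, m) else runif(m)
    got <- if (rep %% 2) unname(featureBlockiness(aln, ss)["F_BL"]) else
      unname(featureBlockiness(aln, ss, weights = w)["F_BL_aug"])
    expect_equal(got, bruteBlockiness(aln, ss, w), tolerance = 1e-9)
  }
})

test_that("the shipped estimator reproduces printed arithmetic", {
  est <- defaultEstimator()
  feats <- stats::setNames(rep(1, 12), coreMSA:::.FEATURES)
  expect_equal(estimateAccuracy(est, feats), 1.088, tolerance = 1e-12)
  expect_equal(estimateAccuracy(est, feats * 0), 0)
  one <- new("EstimatorModel", coefficients = c(F_SA = 1))
  expect_equal(estimateAccuracy(one, feats * 0.37), 0.37)
  expect_error(estimateAccuracy(est, feats[1:3]), "missing feature")
  feats["F_SA"] <- NA
  expect_error(estimateAccuracy(est, feats), "NA")
})

test_that("estimator fitting recovers a planted single-feature model", {
  set.seed(24)
  n <- 40
  X <- matrix(runif(n * 4), n, 4,
              dimnames = list(NULL, c("F_SI", "F_BL", "F_GE", "F_SA")))
  acc <- 0.7 * X[, "F_SI"]
  bench <- rep(1:10, each = 4)
  fit <- fitEstimator(X, acc, bench)
  cf <- estimatorCoefficients(fit)
  expect_equal(unname(cf["F_SI"]), 0.7, tolerance = 1e-6)
  expect_true(all(cf[c("F_BL", "F_GE", "F_SA")] < 1e-6))
  # duplicating training rows leaves the fit unchanged
  fit2 <- fitEstimator(rbind(X, X), c(acc, acc), c(bench, bench + 100))
  expect_equal(estimatorCoefficients(fit2), cf, tolerance = 1e-8)
  expect_error(fitEstimator(X, acc, seq_len(n)), "two or more")
})

test_that("feature ranges hold on random synthetic alignments", {
  fx <- smallSuite()
  bounded <- c("F_SI", "F_AI", "F_AS", "F_SA", "F_GO", "F_GE", "F_BL")
  for (b in 1:3) {
    bm <- fx$benchmarks[[b]]
    for (id in names(bm$computed)[c(1, 4)]) {
      cor <- trueColumnCoreness(bm$computed[[id]], bm$reference,
                                bm$annotation)
      f <- computeFeatures(bm$computed[[id]], bm$ss, coreness = cor)
      expect_true(all(f[bounded] >= 0 & f[bounded] <= 1))
      expect_gte(unname(f["F_AC"]), 0)
      # unit weights collapse augmentation
      f1 <- computeFeatures(bm$computed[[id]], bm$ss,
                            coreness = rep(1, nColumns(bm$computed[[id]])))
      expect_equal(unname(f1["F_SI_aug"]), unname(f1["F_SI"]))
      expect_equal(unname(f1["F_BL_aug"]), unname(f1["F_BL"]))
      expect_equal(unname(f1["F_AI_aug"]), unname(f1["F_AI"]))
      expect_equal(unname(f1["F_AS_aug"]), unname(f1["F_AS"]))
    }
  }
})

test_that("advising picks the argmax and averages within bins first", {
  expect_equal(advise(c(0.3, 0.9, 0.5)), 2L)
  expect_equal(advise(0.4), 1L)
  expect_equal(advise(c(0.7, 0.7, 0.2)), 1L)   # tie: lowest index
  trueAcc <- rbind(c(0.9, 0.4), c(0.2, 0.6), c(0.5, 0.8))
  est <- rbind(c(1, 0), c(0, 1), c(0, 1))
  bins <- c(9L, 1L, 1L)
  r <- evaluateAdvising(trueAcc, est, bins)
  expect_equal(unname(r$advisedAccuracy), c(0.9, 0.6, 0.8))
  expect_equal(unname(r$perBin[["1"]]), 0.7)
  expect_equal(r$score, mean(c(0.7, 0.9)))
  # an oracle advisor dominates any other estimator
  oracle <- evaluateAdvising(trueAcc, trueAcc, bins)
  expect_gte(oracle$score, r$score)
})
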