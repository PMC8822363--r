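test_that("oneSidedP follows the add-one counting rule", {
  expect_equal(oneSidedP(c(1, 2, 3, 4), 2.5), 0.6)   # (1 + 2) / 5
  expect_equal(oneSidedP(rep(0, 1000), 1), 1 / 1001)
  expect_equal(oneSidedP(rep(2, 1000), 1), 1.0)
  expect_error(oneSidedP(numeric(0), 1), "empty")
})

test_that("mantelTest gives the minimal p for self-correlation and is reproducible", {
  r <- random_rdm(8, seed = 5)
  mt <- mantelTest(r, r, nPerm = 300, seed = 7)
  expect_equal(pValue(mt), 1 / 301)
  expect_equal(observedStatistic(mt), 1.0)

  mt2 <- mantelTest(r, r, nPerm = 300, seed = 7)
  expect_identical(nullSample(mt2), nullSample(mt))  # bit-reproducible
  expect_equal(mt@nPerm, 300L)
  expect_equal(mt@seed, 7L)

  expect_error(mantelTest(random_rdm(3), random_rdm(3)), "at least 4")
})

test_that("Monte-Carlo Mantel p approaches the exhaustive 24-permutation p", {
  a <- random_rdm(4, p = 10, seed = 11)
  b <- random_rdm(4, p = 10, seed = 12)
  exact <- mantelTestExact(a, b)
  expect_equal(exact@nPerm, 24L)
  mc <- mantelTest(a, b, nPerm = 2000, seed = 13)
  expect_lt(abs(pValue(mc) - pValue(exact)), 0.06)
})

test_that("correlation-difference test behaves under null and signal", {
  shared <- random_rdm(20, seed = 21)
  x <- random_rdm(20, seed = 22)

  # x = y: exchangeable difference, observed exactly 0
  t0 <- rdmCorrelationDifferenceTest(shared, x, x, nPerm = 100, seed = 1)
  expect_equal(observedStatistic(t0), 0)
  expect_gte(pValue(t0), 0.3)

  # x = shared (rho 1) vs independent y: strong positive difference
  t1 <- rdmCorrelationDifferenceTest(shared, shared, x, nPerm = 1000,
                                     seed = 2)
  expect_lte(pValue(t1), 0.01)

  # swapping x and y negates the observed statistic exactly
  y <- random_rdm(20, seed = 23)
  txy <- rdmCorrelationDifferenceTest(shared, x, y, nPerm = 50, seed = 3)
  tyx <- rdmCorrelationDifferenceTest(shared, y, x, nPerm = 50, seed = 3)
  expect_equal(observedStatistic(txy), -observedStatistic(tyx))
})

test_that("across-layer variation test is null at its minimum and detects divergence", {
  a <- random_rdm(12, seed = 31)
  b <- random_rdm(12, seed = 32)
  # identical RDM pair replicated across layers: statistic 0, every null >= 0
  t0 <- acrossLayerVariationTest(list(a, a, a), list(b, b, b),
                                 nPerm = 100, seed = 1)
  expect_equal(observedStatistic(t0), 0)
  expect_equal(pValue(t0), 1.0)

  cfg <- syntheticConfig(nObjects = 42, layers = c(l1 = 64, l2 = 64, l3 = 64),
                         sharedFraction = c(0.2, 0.9, 0.2), noiseSd = 0.05,
                         seed = 33)
  rd <- layerDepictionRDMs(generateActivations(cfg))
  tv <- acrossLayerVariationTest(lapply(rd, `[[`, "photo"),
                                 lapply(rd, `[[`, "drawing"),
                                 nPerm = 200, seed = 2)
  expect_lte(pValue(tv), 0.05)

  expect_error(acrossLayerVariationTest(list(a), list(b)), "2 layers")
})

test_that("sign permutation test flips accuracy signs as specified", {
  # all-zero accuracies: flipping zeros changes nothing, p = 1 for cnn > 0
  t0 <- signPermutationTest(rep(0, 20), cnnAcc = 0.3, nPerm = 200, seed = 1)
  expect_equal(pValue(t0), 1.0)

  # all-ones human vs 0.5 network: observed is the unique maximum
  t1 <- signPermutationTest(rep(1, 42), cnnAcc = 0.5, nPerm = 1000, seed = 2)
  expect_equal(pValue(t1), 1 / 1001)

  # add-one minimum cannot increase with more permutations
  t2 <- signPermutationTest(rep(1, 42), cnnAcc = 0.5, nPerm = 2000, seed = 3)
  expect_lte(pValue(t2), pValue(t1))

  # difference-flipping variant exposed behind a flag
  t3 <- signPermutationTest(runif(30), cnnAcc = 0.4, nPerm = 100, seed = 4,
                            flipDifferences = TRUE)
  expect_s4_class(t3, "PermutationResult")
  expect_error(signPermutationTest(numeric(0), 0.5), "empty")
})

test_that("mcnemarTest matches the closed form and the reference implementation", {
  # b = c = 3: chi2 = 0, p = 1
  tab0 <- rbind(matrix(c(1, 0), 3, 2, byrow = TRUE),
                matrix(c(0, 1), 3, 2, byrow = TRUE),
                matrix(c(1, 1), 4, 2, byrow = TRUE))
  r0 <- mcnemarTest(tab0)
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)

  # b = 5, c = 1: chi2 = 16/6
  tab1 <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
                matrix(c(0, 1), 1, 2, byrow = TRUE),
                matrix(c(1, 1), 6, 2, byrow = TRUE))
  r1 <- mcnemarTest(tab1)
  expect_equal(r1$chi2, 16 / 6, tolerance = 1e-12)

  # cross-check against the uncorrected reference implementation
  ct <- table(factor(tab1[, 1], 0:1), factor(tab1[, 2], 0:1))
  ref <- stats::mcnemar.test(ct, correct = FALSE)
  expect_equal(r1$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r1$p, ref$p.value, tolerance = 1e-12)

  # swapping conditions leaves chi2 unchanged
  r1s <- mcnemarTest(tab1[, 2:1])
  expect_equal(r1s$chi2, r1$chi2)

  expect_error(mcnemarTest(matrix(c(1, 1, 1, 1), 2, 2)), "undefined")
  expect_error(mcnemarTest(matrix(c(2, 0, 1, 0), 2, 2)), "binary")
})

test_that("TOST equivalence test behaves at bounds and degeneracies", {
  # identical samples: zero difference well inside the bounds
  x <- runif(42)
  r0 <- tostEquivalence(x, x, bounds = c(-0.05, 0.05))
  expect_lt(r0$p, 0.001)
  expect_true(r0$decision)

  # mean difference exactly at the upper bound: that one-sided t is 0
  set.seed(51)
  e <- rnorm(2000, sd = 0.1); e <- e - mean(e)
  y1 <- e + 0.05
  r1 <- tostEquivalence(y1, rep(0, 2000), bounds = c(-0.05, 0.05))
  expect_equal(r1$p, 0.5, tolerance = 1e-12)

  # shrinking bounds toward 0 is monotone non-decreasing in p
  set.seed(52)
  d <- rnorm(40, mean = 0.01, sd = 0.05)
  widths <- c(0.1, 0.05, 0.02, 0.01)
  ps <- vapply(widths, function(w)
    tostEquivalence(d, rep(0, 40), bounds = c(-w, w))$p, numeric(1))
  expect_true(all(diff(ps) >= -1e-12))

  # zero-variance degenerate limits
  expect_equal(tostEquivalence(rep(0.01, 5), rep(0, 5),
                               bounds = c(-0.05, 0.05))$p, 0)
  expect_equal(tostEquivalence(rep(0.2, 5), rep(0, 5),
                               bounds = c(-0.05, 0.05))$p, 1)
})

test_that("independentTTest matches the pooled-variance closed form", {
  r <- independentTTest(c(1, 2, 3), c(4, 5, 6))
  # pooled sd = 1, se = sqrt(2/3), t = -3/se
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-9)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$df, 4)

  x <- rnorm(10); y <- rnorm(12)
  r1 <- independentTTest(x, y)
  r2 <- independentTTest(3 * x, 3 * y)
  expect_equal(r1$t, r2$t, tolerance = 1e-12)

  same <- c(1, 2, 3)
  rs <- independentTTest(same, same)
  expect_equal(rs$t, 0)
  expect_equal(rs$p, 1)
})

test_that("bhFDR implements the step-up adjustment", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(c(0.001, 0.5)), c(0.002, 0.5))
  expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")

  # sorting inputs sorts outputs identically
  set.seed(61)
  p <- runif(20)
  expect_equal(sort(bhFDR(p)), bhFDR(sort(p)))

  fam <- data.frame(p = c(0.01, 0.02, 0.03, 0.04, 0.001, 0.5),
                    family = rep(c("a", "b"), c(4, 2)))
  adj <- fdrWithinFamilies(fam)
  expect_equal(adj$p_adj, c(rep(0.04, 4), 0.002, 0.5))
})

test_that("decodingPermutationNull detects separable classes and records provenance", {
  set.seed(71)
  n <- 42
  y <- rep(c("m", "n"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6) + ifelse(y == "m", 6, -6)
  cfg <- decodeConfig(nTest = 6, nIter = 10, seed = 1)
  pr <- decodingPermutationNull(x, y, config = cfg, nPerm = 99, seed = 5)
  expect_equal(pValue(pr), 1 / 100)        # add-one minimum
  expect_equal(observedStatistic(pr), 1.0)
  expect_equal(pr@seed, 5L)
  # chance level of the null for balanced labels
  expect_equal(mean(nullSample(pr)), 0.5, tolerance = 0.03)
})
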