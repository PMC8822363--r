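test_that("syntheticConfig enforces its invariants", {
  expect_error(syntheticConfig(sharedFraction = 1.2), "alpha")
  expect_error(syntheticConfig(nObjects = 10, nManmade = 11), "nManmade")
  expect_error(syntheticConfig(latentDim = 1), "dimensionalities")
  expect_error(syntheticConfig(noiseSd = -1), "noiseSd")
  cfg <- syntheticConfig()
  expect_equal(cfg$nObjects, 42L)
  expect_equal(cfg$nManmade, 21L)
  expect_equal(cfg$depictions, c("photo", "drawing", "sketch"))
})

test_that("stimulus metadata has every object once per depiction", {
  cfg <- syntheticConfig(nObjects = 6, nManmade = 3, layers = c(l1 = 8),
                         seed = 1)
  meta <- syntheticMetadata(cfg)
  expect_equal(nrow(meta), 18)
  expect_false(anyDuplicated(meta[, c("object_id", "depiction")]) > 0)
  tab <- table(meta$object_id, meta$depiction)
  expect_true(all(tab == 1))
  expect_equal(sum(meta$superordinate == "manmade"), 9)
})

test_that("generateActivations is bit-reproducible given the seed", {
  cfg <- syntheticConfig(nObjects = 6, nManmade = 3, layers = c(a = 8, b = 8),
                         sharedFraction = 0.5, seed = 123)
  m1 <- generateActivations(cfg)
  m2 <- generateActivations(cfg)
  expect_identical(m1@layers, m2@layers)
  m3 <- generateActivations(syntheticConfig(nObjects = 6, nManmade = 3,
                                            layers = c(a = 8, b = 8),
                                            sharedFraction = 0.5,
                                            seed = 124))
  expect_false(identical(m1@layers$a, m3@layers$a))
})

test_that("alpha = 1 with zero noise yields perfect cross-depiction correlation", {
  cfg <- syntheticConfig(nObjects = 9, nManmade = 4, layers = c(l1 = 20),
                         sharedFraction = 1, noiseSd = 0, seed = 6)
  sp <- splitByDepiction(getLayer(generateActivations(cfg), "l1"))
  expect_equal(rdmSpearman(computeRDM(sp$photo), computeRDM(sp$drawing)),
               1.0)
})

test_that("alpha = 0 yields near-zero mean cross-depiction correlation", {
  rhos <- vapply(1:10, function(s) {
    cfg <- syntheticConfig(nObjects = 20, nManmade = 10, layers = c(l1 = 40),
                           sharedFraction = 0, noiseSd = 0.05, seed = s)
    sp <- splitByDepiction(getLayer(generateActivations(cfg), "l1"))
    rdmSpearman(computeRDM(sp$photo), computeRDM(sp$drawing))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("triplet simulator chooses the unique argmin deterministically", {
  S <- matrix(0.1, 3, 3)
  S[1, 2] <- S[2, 1] <- 0.9
  diag(S) <- 1
  dimnames(S) <- list(c("x", "y", "z"), c("x", "y", "z"))
  tr <- generateTripletTrials(S, mode = "sampled", nTrials = 50,
                              choiceModel = "deterministic", seed = 3)
  expect_true(all(tr$chosen == "z"))
  expect_error(generateTripletTrials(S[1:2, 1:2]), "at least 3")
})

test_that("exhaustive mode enumerates each unordered triple exactly once", {
  S <- diag(7) * 0 + 0.5; diag(S) <- 1
  tr <- generateTripletTrials(S, mode = "exhaustive", seed = 1)
  expect_equal(nrow(tr), choose(7, 3))
  key <- apply(tr[, 1:3], 1, function(r) paste(sort(r), collapse = "+"))
  expect_false(any(duplicated(key)))
})

test_that("ties are broken uniformly under the seed", {
  S <- matrix(0.5, 6, 6); diag(S) <- 1
  tr <- generateTripletTrials(S, mode = "sampled", nTrials = 3000,
                              choiceModel = "deterministic", seed = 17)
  # every object of a triplet is equally likely to be the tie-broken choice:
  # chosen-to-appearance ratio is 1/3 per object
  appearances <- table(unlist(tr[, 1:3]))
  freq <- table(tr$chosen)[names(appearances)] / appearances
  expect_true(all(abs(freq - 1 / 3) < 0.05))
  # reproducible
  tr2 <- generateTripletTrials(S, mode = "sampled", nTrials = 3000,
                               choiceModel = "deterministic", seed = 17)
  expect_identical(tr, tr2)
})

test_that("paired outcomes honor marginals and concordance", {
  # p_a = p_b = 1: all pairs (1,1), zero discordance
  t1 <- generatePairedOutcomes(50, 1, 1, "independent", seed = 1)
  expect_true(all(t1$a == 1 & t1$b == 1))

  # equal marginals with maximal concordance: b = c = 0
  t2 <- generatePairedOutcomes(500, 0.8, 0.8, "maximal", seed = 2)
  expect_equal(sum(t2$a != t2$b), 0)

  # independence: empirical marginals and cell b near closed form
  t3 <- generatePairedOutcomes(1000, 0.7, 0.5, "independent", seed = 3)
  expect_equal(mean(t3$a), 0.7, tolerance = 0.03)
  expect_equal(mean(t3$b), 0.5, tolerance = 0.03)
  b_hat <- mean(t3$a == 1 & t3$b == 0)
  expect_lt(abs(b_hat - 0.7 * 0.5), 0.04)

  expect_error(generatePairedOutcomes(10, 0.9, 0.2, concordance = 0.05),
               "feasible range")
})

test_that("synthetic image variants share geometry but differ in rendering", {
  s1 <- generateImages(nObjects = 3, canvas = 48, seed = 4)
  expect_identical(names(s1$polygons), sprintf("obj%03d", 1:3))
  # the two variants are built from the exact same polygon
  expect_equal(length(s1$images), 6)
  expect_equal(s1$metadata$depiction, rep(c("photo", "drawing"), 3))

  # contour variant is mostly background
  contour <- s1$images[["obj001|drawing"]]
  frac_bg <- mean(abs(contour[, , 1] - 0.5) < 1e-9)
  expect_gte(frac_bg, 0.8)

  # different seeds give different vertex sets
  s2 <- generateImages(nObjects = 3, canvas = 48, seed = 5)
  expect_false(isTRUE(all.equal(s1$polygons[[1]], s2$polygons[[1]])))

  expect_error(generateImages(nObjects = 1), "at least 2")
  expect_error(generateImages(nObjects = 3, canvas = 4), "degenerate")
})

test_that("activation container round-trips through CSV", {
  cfg <- syntheticConfig(nObjects = 5, nManmade = 2, layers = c(a = 6, b = 7),
                         sharedFraction = 0.5, seed = 31)
  m <- generateActivations(cfg)
  d <- file.path(tempdir(), "acts_roundtrip")
  writeActivations(m, d)
  m2 <- readActivations(d)
  expect_equal(layerNames(m2), layerNames(m))
  expect_equal(m2@layers$a, m@layers$a, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m2@meta$object_id, m@meta$object_id)
})
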