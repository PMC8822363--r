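test_that("tripletSimilarity counts kept-together ratios per the definition", {
  # pair (x, y) co-occurs in 4 trials; the third object is chosen in 3 of
  # them (in trial 3 the chooser picks y, so the pair is split)
  trials <- data.frame(
    object_a = c("x", "x", "x", "x"),
    object_b = c("y", "y", "y", "y"),
    object_c = c("z", "w", "z", "w"),
    chosen   = c("z", "w", "y", "w"),
    stringsAsFactors = FALSE)
  est <- tripletSimilarity(trials)
  sim <- choiceSimilarity(est)
  expect_equal(sim["x", "y"], 3 / 4)
  expect_equal(choiceCounts(est)["x", "y"], 4)

  # pair (x, z) co-occurs in trials 1 and 3; kept together only in trial 3
  # (where the remaining object y was the odd one out)
  expect_equal(choiceCounts(est)["x", "z"], 2)
  expect_equal(sim["x", "z"], 0.5)
})

test_that("never co-occurring pairs are flagged undefined, not zero", {
  trials <- data.frame(object_a = "a", object_b = "b", object_c = "c",
                       chosen = "c", stringsAsFactors = FALSE)
  est <- tripletSimilarity(trials, labels = c("a", "b", "c", "d"))
  sim <- choiceSimilarity(est)
  expect_true(is.na(sim["a", "d"]))
  expect_equal(sim["a", "b"], 1)
  expect_error(choiceSimilarityToRDM(est), "\\(a, d\\)")
})

test_that("estimator is invariant to trial order and within-trial object order", {
  S <- planted_similarity(6, seed = 2)
  trials <- generateTripletTrials(S, mode = "exhaustive", seed = 1)
  est1 <- tripletSimilarity(trials, labels = rownames(S))

  shuffled <- trials[sample(nrow(trials)), ]
  est2 <- tripletSimilarity(shuffled, labels = rownames(S))
  expect_equal(est2@sim, est1@sim)

  swapped <- trials
  swapped$object_a <- trials$object_b
  swapped$object_b <- trials$object_a
  est3 <- tripletSimilarity(swapped, labels = rownames(S))
  expect_equal(est3@sim, est1@sim)
})

test_that("choiceSimilarityToRDM applies d = 1 - sim with zero diagonal", {
  trials <- data.frame(
    object_a = c("a", "a", "b"), object_b = c("b", "b", "c"),
    object_c = c("c", "c", "a"), chosen = c("c", "c", "c"))
  est <- tripletSimilarity(trials)
  r <- choiceSimilarityToRDM(est)
  v <- rdmValues(r)
  expect_equal(v["a", "b"], 0)       # sim 1 -> d 0
  expect_equal(diag(v), c(a = 0, b = 0, c = 0))

  # constant similarity: downstream Spearman is flagged undefined
  simm <- matrix(0.5, 4, 4); diag(simm) <- 1
  cnt <- matrix(6L, 4, 4); diag(cnt) <- 0L
  const <- new("PairwiseChoiceSimilarity", labels = letters[1:4],
               sim = simm, counts = cnt)
  rc <- choiceSimilarityToRDM(const)
  expect_warning(out <- rdmSpearman(rc, rc), "undefined")
  expect_true(is.na(out))
})

test_that("estimator matches the brute-force enumeration oracle and recovers ranking", {
  S <- planted_similarity(8, seed = 3)
  trials <- generateTripletTrials(S, mode = "exhaustive",
                                  choiceModel = "deterministic", seed = 4)
  est <- tripletSimilarity(trials, labels = rownames(S))
  oracle <- oracle_triplet_similarity(trials, rownames(S))
  expect_equal(unname(choiceSimilarity(est)), unname(oracle),
               tolerance = 1e-12)

  rho <- cor(upper_vec(est@sim), upper_vec(S), method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("more sampled trials weakly improve rank agreement with the planted similarity", {
  budgets <- c(200, 800, 3000)
  agree <- sapply(1:10, function(s) {
    S <- planted_similarity(8, seed = s)
    vapply(budgets, function(b) {
      tr <- generateTripletTrials(S, mode = "sampled", nTrials = b,
                                  choiceModel = "deterministic",
                                  seed = 100 + s)
      est <- tripletSimilarity(tr, labels = rownames(S))
      ok <- !is.na(upper_vec(est@sim))
      cor(upper_vec(est@sim)[ok], upper_vec(S)[ok], method = "spearman")
    }, numeric(1))
  })
  means <- rowMeans(agree)
  expect_true(all(diff(means) >= -0.02))
  expect_gt(means[3], means[1])
})

test_that("labelAccuracy scores exact and synonym matches case-insensitively", {
  key <- data.frame(
    object_id = c("o1", "o1", "o2", "o2", "o3"),
    synonym = c("dog", "hound", "car", "automobile", "tree"))
  responses <- data.frame(
    object_id = rep(c("o1", "o2", "o3"), each = 4),
    response = c("Dog", "hound", "DOG ", "puppy",     # 3/4
                 "car", "Automobile", "car", "truck", # 3/4... adjusted below
                 "tree", "bush", "shrub", "plant"))   # 1/4
  res <- labelAccuracy(responses, key)
  expect_equal(unname(res$perObject[c("o1", "o2", "o3")]),
               c(0.75, 0.75, 0.25))
  expect_equal(res$mean, mean(c(0.75, 0.75, 0.25)))

  bad <- data.frame(object_id = "o9", response = "dog")
  expect_error(labelAccuracy(bad, key), "o9")
})

test_that("hand-counted labeling fixture gives per-object accuracies (1.0, 0.75, 0.5)", {
  key <- data.frame(object_id = rep(c("a", "b", "c"), each = 2),
                    synonym = c("ant", "emmet", "bee", "honeybee",
                                "cat", "feline"))
  responses <- data.frame(
    object_id = rep(c("a", "b", "c"), each = 4),
    response = c("ant", "Emmet", "ANT", "ant",
                 "bee", "honeybee", "bee", "wasp",
                 "cat", "feline", "dog", "kitten"))
  res <- labelAccuracy(responses, key)
  expect_equal(unname(res$perObject[c("a", "b", "c")]), c(1.0, 0.75, 0.5))
})
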