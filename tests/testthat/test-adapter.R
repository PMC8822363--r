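test_that("preprocessImage produces a normalized square canvas", {
  cfg <- preprocessConfig()   # defaults: 224 canvas
  img <- generateImages(nObjects = 2, canvas = 48, seed = 1)$images[[1]]
  out <- preprocessImage(img, cfg)
  expect_equal(dim(out), c(224, 224, 3))

  # all-background input maps to the constant normalized gray value
  flat <- array(0.5, dim = c(40, 40, 3))
  outf <- preprocessImage(flat, cfg)
  for (ch in 1:3)
    expect_equal(unique(as.vector(outf[, , ch])),
                 (0.5 - cfg$means[ch]) / cfg$sds[ch], tolerance = 1e-12)
})

test_that("preprocessImage preserves foreground aspect ratio within a pixel", {
  cfg <- preprocessConfig(canvas = 64)
  # off-center rectangle with a 2:1 bounding box
  img <- array(0.5, dim = c(60, 80, 3))
  img[5:24, 11:20, ] <- 0.9         # 20 rows x 10 cols
  out <- preprocessImage(img, cfg)
  # recover the foreground on the processed canvas
  un <- out[, , 1] * cfg$sds[1] + cfg$means[1]
  fg <- abs(un - 0.5) > 0.05
  rows <- diff(range(which(apply(fg, 1, any)))) + 1
  cols <- diff(range(which(apply(fg, 2, any)))) + 1
  expect_lt(abs(rows / cols - 2), 2 / cols + 0.15)

  # alpha channel takes precedence for foreground detection
  rgba <- array(0.5, dim = c(30, 30, 4))
  rgba[, , 4] <- 0
  rgba[10:20, 10:20, 4] <- 1
  outa <- preprocessImage(rgba, cfg)
  expect_equal(attr(outa, "foreground"), "alpha")

  expect_error(preprocessImage("no/such/file.png"), "unreadable")
})

test_that("extractFeatures flattens layer activations with the expected dimensions", {
  net <- tinyCNN(inputShape = c(3L, 16L, 16L), convChannels = c(4L, 8L),
                 fcUnits = 12L, seed = 2)
  imgs <- list(a = array(runif(16 * 16 * 3), c(16, 16, 3)),
               b = array(runif(16 * 16 * 3), c(16, 16, 3)))
  feats <- extractFeatures(net, imgs, c("pool1", "pool2", "fc1"))
  # pooling-layer feature dimension = channels x height x width
  expect_equal(ncol(feats@layers$pool1), 4 * 8 * 8)
  expect_equal(ncol(feats@layers$pool2), 8 * 4 * 4)
  expect_equal(ncol(feats@layers$fc1), 12)
  expect_equal(nrow(feats@layers$pool1), 2)

  # identical inputs give identical rows at every layer
  dup <- extractFeatures(net, list(x = imgs$a, y = imgs$a), c("pool1", "fc1"))
  expect_equal(dup@layers$pool1[1, ], dup@layers$pool1[2, ])
  expect_equal(dup@layers$fc1[1, ], dup@layers$fc1[2, ])

  expect_error(extractFeatures(net, imgs, "pool9"), "available")
})

test_that("backpropagated gradients match finite differences", {
  net <- tinyCNN(inputShape = c(1L, 8L, 8L), convChannels = c(2L),
                 fcUnits = 4L, nClasses = 2L, seed = 3)
  x <- array(runif(64), c(1, 8, 8))
  y <- 1L
  loss_of <- function(n) {
    z <- depictRSA:::cnn_forward(n, x)$logits
    z <- z - max(z)
    -log(exp(z[y]) / sum(exp(z)))
  }
  fw <- depictRSA:::cnn_forward(net, x, cache = TRUE)
  z <- fw$logits - max(fw$logits)
  probs <- exp(z) / sum(exp(z))
  dlog <- probs; dlog[y] <- dlog[y] - 1
  grads <- depictRSA:::cnn_backward(net, fw$caches, dlog)

  eps <- 1e-5
  for (lname in c("conv1", "fc1", "fc2")) {
    W <- net@layers[[lname]]$W
    for (idx in sample(length(W), 4)) {
      np <- net; np@layers[[lname]]$W[idx] <- W[idx] + eps
      nm <- net; nm@layers[[lname]]$W[idx] <- W[idx] - eps
      num <- (loss_of(np) - loss_of(nm)) / (2 * eps)
      expect_equal(grads[[lname]]$dW[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("finetune freezes the boundary and learns a separable task", {
  set.seed(5)
  mk_img <- function(bright) {
    base <- if (bright) 0.8 else 0.2
    array(base + runif(8 * 8 * 3, -0.1, 0.1), c(8, 8, 3))
  }
  labels <- rep(1:2, each = 20)
  imgs <- lapply(labels == 1, mk_img)
  train <- list(images = imgs[c(1:14, 21:34)],
                labels = labels[c(1:14, 21:34)])
  val <- list(images = imgs[c(15:20, 35:40)], labels = labels[c(15:20, 35:40)])

  net <- tinyCNN(inputShape = c(3L, 8L, 8L), convChannels = c(2L, 4L),
                 fcUnits = 8L, nClasses = 2L, seed = 6)
  cfg <- finetuneConfig(freezeBoundary = "pool1", learningRate = 0.05,
                        momentum = 0.7, epochs = 8, batchSize = 7, seed = 7)
  out <- finetune(net, train, val, cfg)

  # frozen parameters are bit-for-bit identical
  expect_identical(out$network@layers$conv1$W, net@layers$conv1$W)
  expect_identical(out$network@layers$conv1$b, net@layers$conv1$b)
  # trained parameters moved
  expect_false(identical(out$network@layers$fc2$W, net@layers$fc2$W))
  # learns the separable task above chance
  expect_gt(out$valAccuracy[length(out$valAccuracy)], 0.5)
  expect_length(out$valAccuracy, 8)

  # learning rate 0 leaves every parameter unchanged
  cfg0 <- finetuneConfig(freezeBoundary = "pool1", learningRate = 0,
                         epochs = 2, seed = 8)
  out0 <- finetune(net, train, val, cfg0)
  expect_identical(out0$network@layers, net@layers)

  expect_error(finetune(net, list(images = list()), val, cfg), "empty")
  expect_error(finetuneConfig(freezeBoundary = "x", learningRate = -1),
               "nonnegative")
  expect_error(finetune(net, train, val,
                        finetuneConfig(freezeBoundary = "nope")),
               "existing layer")
})

test_that("hierarchy-aware top-1 accuracy uses the hyponym closure", {
  edges <- data.frame(child = c("poodle", "beagle", "tabby"),
                      parent = c("dog", "dog", "cat"))
  idx_map <- c("1" = "poodle", "2" = "beagle", "3" = "tabby", "4" = "dog",
               "5" = "cat")
  tax <- taxonomyGraph(edges, indexMap = idx_map)
  expect_setequal(hyponyms(tax, "dog"), c("poodle", "beagle"))

  # prediction poodle for target dog is correct (hyponym); exact match too
  acc <- top1AccuracyHierarchy(c(1, 4), c("dog", "dog"), tax)
  expect_equal(as.numeric(acc), 1.0)

  # 5-item fixture with 3 in-closure predictions
  preds <- c(1, 2, 3, 3, 5)   # poodle, beagle, tabby, tabby, cat
  targs <- c("dog", "dog", "dog", "cat", "dog")
  acc5 <- top1AccuracyHierarchy(preds, targs, tax)
  expect_equal(as.numeric(acc5), 0.6)

  # a taxonomy with no edges among the classes reduces to exact match
  lone <- taxonomyGraph(data.frame(child = "x", parent = "y"),
                        indexMap = c("1" = "a", "2" = "b"))
  expect_equal(as.numeric(top1AccuracyHierarchy(c(1, 2), c("b", "b"), lone)),
               0.5)

  expect_error(top1AccuracyHierarchy(c(9), "dog", tax), "unmapped")
  expect_error(top1AccuracyHierarchy(c(1), "unicorn", tax), "missing")
  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(taxonomyGraph(cyc), "acyclic")
})

test_that("synthetic images flow through the full adapter + RSA pipeline", {
  gen <- generateImages(nObjects = 6, canvas = 48, seed = 9)
  cfg <- preprocessConfig(canvas = 32)
  proc <- lapply(gen$images, preprocessImage, config = cfg)
  net <- tinyCNN(inputShape = c(3L, 32L, 32L), convChannels = c(4L, 8L),
                 fcUnits = 10L, seed = 10)
  feats <- extractFeatures(net, proc, c("pool1", "pool2", "fc1"),
                           meta = gen$metadata)
  prof <- crossDepictionProfile(feats)
  expect_true(all(is.finite(prof$rho)))
  expect_equal(nrow(prof), 3)  # 3 layers x 1 depiction pair

  # duplicated image lists yield exact-duplicate blocks at distance 0
  dup_feats <- extractFeatures(net, c(proc[1], proc[1], proc[2]), "pool1")
  r <- computeRDM(dup_feats@layers$pool1)
  expect_equal(rdmValues(r)[1, 2], 0, tolerance = 1e-12)
})
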