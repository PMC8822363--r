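#' Create a tiny random convolutional network
#'
#' A compact reference network — conv / ReLU / max-pool blocks followed by
#' two fully connected layers with a softmax readout — used to exercise the
#' adapter operations (layerwise feature extraction, hierarchy-aware scoring,
#' layer-frozen fine-tuning) without any external deep-learning backend.
#' Convolutions use 'same' padding; pooling is 2x2 max with stride 2, so
#' spatial dimensions must be divisible by 2 at every pooling stage.
#'
#' @param inputShape integer c(channels, height, width).
#' @param convChannels output channels of each conv block (one pool per
#'   block).
#' @param kernel odd conv kernel size (default 3).
#' @param fcUnits hidden units of the first fully connected layer.
#' @param nClasses output classes.
#' @param seed RNG seed for the weight initialization.
#' @return a \linkS4class{TinyCNN} with layers named conv1, relu1, pool1,
#'   conv2, ..., flatten, fc1, relu_fc1, fc2.
#' @export
tinyCNN <- function(inputShape = c(3L, 16L, 16L), convChannels = c(4L, 8L),
                    kernel = 3L, fcUnits = 16L, nClasses = 2L, seed = 1) {
  stopifnot(length(inputShape) == 3, kernel %% 2 == 1)
  with_seed(seed, {
    layers <- list()
    cin <- inputShape[1]; h <- inputShape[2]; w <- inputShape[3]
    for (bi in seq_along(convChannels)) {
      cout <- convChannels[bi]
      fan_in <- cin * kernel * kernel
      layers[[paste0("conv", bi)]] <- list(
        type = "conv",
        W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                   cout, fan_in),
        b = numeric(cout), cin = cin, cout = cout, k = kernel)
      layers[[paste0("relu", bi)]] <- list(type = "relu")
      if (h %% 2 != 0 || w %% 2 != 0)
        stop("spatial size must be even at every pooling stage")
      layers[[paste0("pool", bi)]] <- list(type = "pool")
      cin <- cout; h <- h %/% 2; w <- w %/% 2
    }
    layers[["flatten"]] <- list(type = "flatten")
    flat <- cin * h * w
    layers[["fc1"]] <- list(
      type = "fc",
      W = matrix(stats::rnorm(fcUnits * flat, sd = sqrt(2 / flat)),
                 fcUnits, flat),
      b = numeric(fcUnits))
    layers[["relu_fc1"]] <- list(type = "relu")
    layers[["fc2"]] <- list(
      type = "fc",
      W = matrix(stats::rnorm(nClasses * fcUnits, sd = sqrt(2 / fcUnits)),
                 nClasses, fcUnits),
      b = numeric(nClasses))
    new("TinyCNN", layers = layers, inputShape = as.integer(inputShape))
  })
}

# --- forward/backward primitives (x is an array c(C, H, W)) ----------------

im2col <- function(x, k) {
  d <- dim(x); cin <- d[1]; h <- d[2]; w <- d[3]
  pad <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(cin, h + 2 * pad, w + 2 * pad))
  xp[, (pad + 1):(pad + h), (pad + 1):(pad + w)] <- x
  P <- matrix(0, cin * k * k, h * w)
  r <- 0L
  for (ci in seq_len(cin)) for (dh in seq_len(k)) for (dw in seq_len(k)) {
    r <- r + 1L
    P[r, ] <- as.vector(xp[ci, dh:(dh + h - 1), dw:(dw + w - 1)])
  }
  P
}

col2im <- function(dP, cin, k, h, w) {
  pad <- (k - 1L) %/% 2L
  dxp <- array(0, dim = c(cin, h + 2 * pad, w + 2 * pad))
  r <- 0L
  for (ci in seq_len(cin)) for (dh in seq_len(k)) for (dw in seq_len(k)) {
    r <- r + 1L
    dxp[ci, dh:(dh + h - 1), dw:(dw + w - 1)] <-
      dxp[ci, dh:(dh + h - 1), dw:(dw + w - 1)] + matrix(dP[r, ], h, w)
  }
  dxp[, (pad + 1):(pad + h), (pad + 1):(pad + w), drop = FALSE]
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  P <- im2col(x, layer$k)
  out <- layer$W %*% P + layer$b
  list(out = array(aperm(array(t(out), dim = c(d[2], d[3], layer$cout)),
                         c(3, 1, 2)),
                   dim = c(layer$cout, d[2], d[3])),
       cache = list(P = P, h = d[2], w = d[3]))
}

conv_backward <- function(layer, cache, dout) {
  hw <- cache$h * cache$w
  dmat <- matrix(aperm(dout, c(2, 3, 1)), nrow = hw, ncol = layer$cout)
  dmat <- t(dmat)                       # cout x hw
  dW <- dmat %*% t(cache$P)
  db <- rowSums(dmat)
  dP <- t(layer$W) %*% dmat
  dx <- col2im(dP, layer$cin, layer$k, cache$h, cache$w)
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x); cin <- d[1]; h <- d[2]; w <- d[3]
  ho <- h %/% 2L; wo <- w %/% 2L
  out <- array(0, dim = c(cin, ho, wo))
  amax <- array(0L, dim = c(cin, ho, wo))
  for (ci in seq_len(cin)) {
    m <- matrix(x[ci, , ], h, w)
    a <- m[seq(1, h, 2), seq(1, w, 2), drop = FALSE]
    b <- m[seq(2, h, 2), seq(1, w, 2), drop = FALSE]
    cc <- m[seq(1, h, 2), seq(2, w, 2), drop = FALSE]
    dd <- m[seq(2, h, 2), seq(2, w, 2), drop = FALSE]
    mx <- pmax(a, b, cc, dd)
    out[ci, , ] <- mx
    which4 <- 1L * (a == mx) # first match wins, in order a, b, cc, dd
    which4[which4 == 0 & b == mx] <- 2L
    which4[which4 == 0 & cc == mx] <- 3L
    which4[which4 == 0 & dd == mx] <- 4L
    amax[ci, , ] <- which4
  }
  list(out = out, cache = list(amax = amax, h = h, w = w))
}

pool_backward <- function(cache, dout) {
  d <- dim(dout); cin <- d[1]; ho <- d[2]; wo <- d[3]
  dx <- array(0, dim = c(cin, cache$h, cache$w))
  for (ci in seq_len(cin)) {
    g <- matrix(dout[ci, , ], ho, wo)
    a <- matrix(cache$amax[ci, , ], ho, wo)
    for (q in 1:4) {
      sel <- a == q
      if (!any(sel)) next
      roff <- if (q %in% c(1, 3)) 0L else 1L
      coff <- if (q %in% c(1, 2)) 0L else 1L
      idx <- which(sel, arr.ind = TRUE)
      dx[cbind(ci, 2L * idx[, 1] - 1L + roff, 2L * idx[, 2] - 1L + coff)] <-
        g[sel]
    }
  }
  dx
}

# Forward pass; returns final logits, per-layer outputs (flattened rows for
# feature extraction) and caches for backprop.
cnn_forward <- function(net, x, keep = character(0), cache = FALSE) {
  acts <- list()
  caches <- list()
  cur <- x
  for (nm in names(net@layers)) {
    l <- net@layers[[nm]]
    if (l$type == "conv") {
      cf <- conv_forward(l, cur)
      cur <- cf$out
      if (cache) caches[[nm]] <- cf$cache
    } else if (l$type == "relu") {
      if (cache) caches[[nm]] <- list(mask = cur > 0)
      cur <- pmax(cur, 0)
    } else if (l$type == "pool") {
      pf <- pool_forward(cur)
      cur <- pf$out
      if (cache) caches[[nm]] <- pf$cache
    } else if (l$type == "flatten") {
      if (cache) caches[[nm]] <- list(dims = dim(cur))
      cur <- as.vector(cur)
    } else if (l$type == "fc") {
      if (cache) caches[[nm]] <- list(x = cur)
      cur <- as.vector(l$W %*% cur + l$b)
    }
    if (nm %in% keep) acts[[nm]] <- as.vector(cur)
  }
  list(logits = cur, acts = acts, caches = caches)
}

cnn_backward <- function(net, caches, dlogits) {
  grads <- list()
  d <- dlogits
  for (nm in rev(names(net@layers))) {
    l <- net@layers[[nm]]
    if (l$type == "fc") {
      grads[[nm]] <- list(dW = outer(d, caches[[nm]]$x), db = d)
      d <- as.vector(t(l$W) %*% d)
    } else if (l$type == "flatten") {
      d <- array(d, dim = caches[[nm]]$dims)
    } else if (l$type == "relu") {
      d <- d * caches[[nm]]$mask
    } else if (l$type == "pool") {
      d <- pool_backward(caches[[nm]], d)
    } else if (l$type == "conv") {
      cb <- conv_backward(l, caches[[nm]], d)
      grads[[nm]] <- list(dW = cb$dW, db = cb$db)
      d <- cb$dx
    }
  }
  grads
}

# Coerce an image (H x W x C array, H x W matrix, or already C x H x W with
# attribute "chw") to the network's C x H x W input convention.
as_chw <- function(img, inputShape) {
  if (is.matrix(img)) img <- array(rep(img, inputShape[1]),
                                   dim = c(dim(img), inputShape[1]))
  d <- dim(img)
  if (length(d) != 3) stop("image must be a 2-D or 3-D array")
  if (all(d == inputShape)) return(img)
  if (d[3] == inputShape[1] && d[1] == inputShape[2] &&
      d[2] == inputShape[3])
    return(aperm(img, c(3, 1, 2)))
  stop(sprintf("image shape (%s) incompatible with network input (%s)",
               paste(d, collapse = "x"),
               paste(inputShape, collapse = "x")))
}

#' Extract layerwise activation patterns from a network
#'
#' Runs each image through the network and collects the activations of the
#' named layers, flattening convolutional feature maps to vectors (the
#' feature dimension of a pooling layer equals channels x height x width).
#' Row order follows the input order.
#'
#' @param network a \linkS4class{TinyCNN}.
#' @param images list of images (H x W x C arrays in the network's input
#'   size); names of the form \code{"object|depiction"} populate the
#'   metadata.
#' @param layerNames layers to extract; must exist in the network.
#' @param meta optional stimulus metadata data.frame (object_id, depiction,
#'   superordinate) overriding the name-derived one.
#' @return a \linkS4class{MultiLayerActivationSet}.
#' @export
extractFeatures <- function(network, images, layerNames, meta = NULL) {
  stopifnot(is(network, "TinyCNN"), length(images) >= 1)
  unknown <- setdiff(layerNames, names(network@layers))
  if (length(unknown))
    stop("unknown layer name(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(network@layers), collapse = ", "))
  rows <- lapply(images, function(img) {
    cnn_forward(network, as_chw(img, network@inputShape),
                keep = layerNames)$acts
  })
  layers <- list()
  for (nm in layerNames)
    layers[[nm]] <- do.call(rbind, lapply(rows, `[[`, nm))
  if (is.null(meta)) {
    nms <- names(images) %||% sprintf("img%03d", seq_along(images))
    parts <- strsplit(nms, "|", fixed = TRUE)
    meta <- data.frame(
      object_id = vapply(parts, `[[`, character(1), 1),
      depiction = vapply(parts, function(p)
        if (length(p) > 1) p[2] else "unspecified", character(1)),
      superordinate = "unspecified", stringsAsFactors = FALSE)
  }
  new("MultiLayerActivationSet", layers = layers, meta = meta)
}

#' Class predictions of a TinyCNN
#'
#' @param network a \linkS4class{TinyCNN}.
#' @param images list of input images.
#' @return integer vector of predicted class indices (argmax of the logits).
#' @export
predictTinyCNN <- function(network, images) {
  vapply(images, function(img) {
    which.max(cnn_forward(network, as_chw(img, network@inputShape))$logits)
  }, integer(1))
}

#' Fine-tuning configuration
#'
#' @param freezeBoundary name of the last frozen layer: this layer and all
#'   earlier ones keep their parameters bit-for-bit; later layers are trained.
#' @param learningRate SGD learning rate (default 0.001).
#' @param momentum SGD momentum (default 0.7).
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed RNG seed for shuffling.
#' @return a list of class \code{FinetuneConfig}.
#' @export
finetuneConfig <- function(freezeBoundary, learningRate = 0.001,
                           momentum = 0.7, epochs = 5, batchSize = 8,
                           seed = 1) {
  if (learningRate < 0) stop("learningRate must be nonnegative")
  structure(list(freezeBoundary = freezeBoundary,
                 learningRate = learningRate, momentum = momentum,
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 seed = check_seed(seed)),
            class = "FinetuneConfig")
}

#' Fine-tune a TinyCNN with a frozen layer boundary
#'
#' Stochastic gradient descent with momentum on the softmax cross-entropy,
#' updating only the parameters of layers strictly after
#' \code{freezeBoundary}; earlier parameters are untouched. Deterministic
#' given the config seed.
#'
#' @param network a \linkS4class{TinyCNN}.
#' @param trainSet list with \code{images} (list of arrays) and
#'   \code{labels} (integer class indices starting at 1).
#' @param valSet validation set in the same format (disjoint from training).
#' @param config a \code{\link{finetuneConfig}}.
#' @return list with \code{network} (trained) and \code{valAccuracy}
#'   (per-epoch validation accuracy trace).
#' @export
finetune <- function(network, trainSet, valSet, config) {
  stopifnot(is(network, "TinyCNN"))
  if (!length(trainSet$images)) stop("empty training set")
  lnames <- names(network@layers)
  if (!config$freezeBoundary %in% lnames)
    stop("freezeBoundary must name an existing layer; available: ",
         paste(lnames, collapse = ", "))
  boundary <- match(config$freezeBoundary, lnames)
  trainable <- lnames[seq_along(lnames) > boundary &
                        vapply(network@layers,
                               function(l) l$type %in% c("conv", "fc"),
                               logical(1))]
  x_train <- lapply(trainSet$images, as_chw,
                    inputShape = network@inputShape)
  y_train <- as.integer(trainSet$labels)
  n <- length(x_train)
  vel <- lapply(network@layers[trainable], function(l)
    list(dW = 0 * l$W, db = 0 * l$b))
  names(vel) <- trainable
  net <- network
  trace <- numeric(config$epochs)
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = config$batchSize)) {
        batch <- ord[start:min(start + config$batchSize - 1, n)]
        gsum <- NULL
        for (i in batch) {
          fw <- cnn_forward(net, x_train[[i]], cache = TRUE)
          z <- fw$logits - max(fw$logits)
          probs <- exp(z) / sum(exp(z))
          dlog <- probs
          dlog[y_train[i]] <- dlog[y_train[i]] - 1
          g <- cnn_backward(net, fw$caches, dlog)
          if (is.null(gsum)) gsum <- g
          else for (nm in names(gsum)) {
            gsum[[nm]]$dW <- gsum[[nm]]$dW + g[[nm]]$dW
            gsum[[nm]]$db <- gsum[[nm]]$db + g[[nm]]$db
          }
        }
        for (nm in trainable) {
          bs <- length(batch)
          vel[[nm]]$dW <- config$momentum * vel[[nm]]$dW -
            config$learningRate * gsum[[nm]]$dW / bs
          vel[[nm]]$db <- config$momentum * vel[[nm]]$db -
            config$learningRate * gsum[[nm]]$db / bs
          net@layers[[nm]]$W <- net@layers[[nm]]$W + vel[[nm]]$dW
          net@layers[[nm]]$b <- net@layers[[nm]]$b + vel[[nm]]$db
        }
      }
      preds <- predictTinyCNN(net, valSet$images)
      trace[ep] <- mean(preds == as.integer(valSet$labels))
    }
  })
  list(network = net, valAccuracy = trace)
}
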