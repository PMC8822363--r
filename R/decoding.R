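#' Decoding configuration
#'
#' @param nTest number of left-out test stimuli per iteration (default 6).
#' @param nIter cross-validation iterations (default 1000).
#' @param cost linear SVM cost parameter (default 1).
#' @param scale scale features before the SVM (default FALSE; logged in the
#'   config echo).
#' @param seed RNG seed for the test draws.
#' @return a list of class \code{DecodeConfig}.
#' @export
decodeConfig <- function(nTest = 6, nIter = 1000, cost = 1, scale = FALSE,
                         seed = 1) {
  stopifnot(nTest >= 1, nIter >= 1, cost > 0)
  structure(list(nTest = as.integer(nTest), nIter = as.integer(nIter),
                 cost = cost, scale = scale, seed = check_seed(seed)),
            class = "DecodeConfig")
}

resolve_decode_input <- function(acts, labels) {
  if (is(acts, "ActivationSet")) {
    x <- acts@activations
    if (is.null(labels)) labels <- acts@meta$superordinate
  } else if (is.matrix(acts)) {
    x <- acts
    if (is.null(labels)) stop("labels required for a plain matrix input")
  } else stop("acts must be an ActivationSet or a matrix")
  if (length(labels) != nrow(x))
    stop("labels length must match the number of stimuli")
  list(x = x, labels = as.character(labels))
}

# Shared leave-N-out engine. Test stimuli are drawn uniformly without
# stratification; a draw whose TRAINING split lacks a class is rejected and
# redrawn (counted), while an all-one-class TEST fold is allowed and scored
# as-is. Training rows come from x_train, test rows from x_test (same
# stimulus indexing), which keeps held-out object ids disjoint from training
# in the cross-depiction case.
cv_engine <- function(x_train, x_test, labels, config) {
  n <- nrow(x_train)
  if (config$nTest >= n) stop("nTest must be smaller than the stimulus count")
  y <- factor(labels)
  if (nlevels(y) < 2) stop("both classes must be present in the stimulus set")
  acc <- numeric(config$nIter)
  redrawn <- 0L
  with_seed(config$seed, {
    for (it in seq_len(config$nIter)) {
      repeat {
        test_idx <- sample.int(n, config$nTest)
        if (nlevels(droplevels(y[-test_idx])) == nlevels(y)) break
        redrawn <- redrawn + 1L
        if (redrawn > 10000L)
          stop("could not draw a training fold containing every class")
      }
      fit <- e1071::svm(x_train[-test_idx, , drop = FALSE], y[-test_idx],
                        kernel = "linear", cost = config$cost,
                        scale = config$scale)
      pred <- stats::predict(fit, x_test[test_idx, , drop = FALSE])
      acc[it] <- mean(pred == y[test_idx])
    }
  })
  new("DecodingResult", meanAccuracy = mean(acc),
      standardError = stats::sd(acc) / sqrt(config$nIter),
      accuracies = acc, config = unclass(config), nRedrawn = redrawn)
}

#' Leave-N-out linear SVM decoding within one depiction
#'
#' Per iteration, \code{nTest} stimuli are drawn uniformly without
#' replacement as the test sample; a linear support vector machine
#' (cost = \code{config$cost}, no feature scaling by default) is trained on
#' the remaining patterns to distinguish the classes (e.g. manmade vs.
#' natural) and scored on the left-out sample. Accuracies are averaged over
#' \code{nIter} iterations. Deterministic given the config seed.
#'
#' @param acts an \linkS4class{ActivationSet} (labels default to the
#'   \code{superordinate} column) or a stimuli x features matrix.
#' @param labels class labels, one per stimulus.
#' @param config a \code{\link{decodeConfig}}.
#' @return a \linkS4class{DecodingResult}.
#' @export
cvDecode <- function(acts, labels = NULL, config = decodeConfig()) {
  xy <- resolve_decode_input(acts, labels)
  cv_engine(xy$x, xy$x, xy$labels, config)
}

#' Cross-depiction linear SVM decoding
#'
#' Trains on the activation patterns of one depiction type and tests on the
#' patterns of another. Per iteration, \code{nTest} object ids are held out;
#' the classifier is trained on the remaining objects' patterns from the
#' training depiction and tested on the held-out objects' patterns from the
#' testing depiction, so no object identity is shared between training and
#' test. \code{crossDecode(a, a, ...)} reproduces \code{cvDecode(a, ...)}
#' exactly under the same seed.
#'
#' @param trainActs,testActs \linkS4class{ActivationSet}s sharing object ids
#'   (and class labels) in the same order, or matrices with matching rows.
#' @param labels class labels per object; defaults to the training set's
#'   \code{superordinate}.
#' @param config a \code{\link{decodeConfig}}.
#' @return a \linkS4class{DecodingResult}.
#' @export
crossDecode <- function(trainActs, testActs, labels = NULL,
                        config = decodeConfig()) {
  tr <- resolve_decode_input(trainActs, labels)
  te <- resolve_decode_input(testActs, labels %||% tr$labels)
  if (is(trainActs, "ActivationSet") && is(testActs, "ActivationSet")) {
    if (!identical(trainActs@meta$object_id, testActs@meta$object_id))
      stop("object-id mismatch between training and testing depictions")
  } else if (nrow(tr$x) != nrow(te$x)) {
    stop("object-id mismatch: training and testing sets differ in size")
  }
  cv_engine(tr$x, te$x, tr$labels, config)
}
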