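#' @import methods
NULL

#' ActivationSet: one layer's stimulus response patterns
#'
#' Container for a stimuli x features activation matrix together with aligned
#' stimulus metadata (object identity, depiction type, superordinate class).
#' Rows of the activation matrix correspond 1:1 to rows of the metadata table.
#'
#' @slot activations numeric matrix, one row per stimulus, one column per
#'   feature. Row names, if present, match \code{object_id}.
#' @slot meta \code{data.frame} with columns \code{object_id},
#'   \code{depiction} and \code{superordinate} (\code{"manmade"} or
#'   \code{"natural"}).
#' @aliases ActivationSet
#' @exportClass ActivationSet
setClass("ActivationSet",
  representation(activations = "matrix", meta = "data.frame"))

setValidity("ActivationSet", function(object) {
  msgs <- character(0)
  a <- object@activations
  m <- object@meta
  if (!is.numeric(a)) msgs <- c(msgs, "activations must be numeric")
  if (nrow(a) != nrow(m))
    msgs <- c(msgs, sprintf("activation rows (%d) != metadata rows (%d)",
                            nrow(a), nrow(m)))
  need <- c("object_id", "depiction", "superordinate")
  miss <- setdiff(need, colnames(m))
  if (length(miss))
    msgs <- c(msgs, paste("metadata missing columns:",
                          paste(miss, collapse = ", ")))
  if (length(a) && !all(is.finite(a)))
    msgs <- c(msgs, "activations contain non-finite entries")
  if (!length(miss) && anyDuplicated(m[, c("object_id", "depiction")]))
    msgs <- c(msgs, "(object_id, depiction) pairs must be unique")
  if (length(msgs)) msgs else TRUE
})

#' MultiLayerActivationSet: activations for several network layers
#'
#' A list of stimuli x features matrices (one per layer, feature
#' dimensionality may differ across layers) sharing a single stimulus
#' metadata table. Row order is identical across layers.
#'
#' @slot layers named list of numeric matrices, all with the same number of
#'   rows, in network order.
#' @slot meta shared stimulus metadata \code{data.frame} (see
#'   \linkS4class{ActivationSet}).
#' @aliases MultiLayerActivationSet
#' @exportClass MultiLayerActivationSet
setClass("MultiLayerActivationSet",
  representation(layers = "list", meta = "data.frame"))

setValidity("MultiLayerActivationSet", function(object) {
  msgs <- character(0)
  if (!length(object@layers)) msgs <- c(msgs, "at least one layer required")
  if (is.null(names(object@layers)) || any(names(object@layers) == ""))
    msgs <- c(msgs, "layers must be named")
  n <- nrow(object@meta)
  for (nm in names(object@layers)) {
    l <- object@layers[[nm]]
    if (!is.matrix(l) || !is.numeric(l)) {
      msgs <- c(msgs, sprintf("layer '%s' is not a numeric matrix", nm))
      next
    }
    if (nrow(l) != n)
      msgs <- c(msgs, sprintf("layer '%s' has %d rows, metadata has %d",
                              nm, nrow(l), n))
    if (!all(is.finite(l)))
      msgs <- c(msgs, sprintf("layer '%s' contains non-finite entries", nm))
  }
  if (length(msgs)) msgs else TRUE
})

#' RDM: representational dissimilarity matrix
#'
#' Square symmetric matrix of pairwise dissimilarities between stimuli with a
#' zero diagonal. For the correlation distance (1 - Pearson r) entries lie in
#' [0, 2].
#'
#' @slot labels ordered stimulus identifiers (row/column labels).
#' @slot values square numeric matrix of dissimilarities.
#' @aliases RDM
#' @exportClass RDM
setClass("RDM", representation(labels = "character", values = "matrix"))

setValidity("RDM", function(object) {
  v <- object@values
  msgs <- character(0)
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "values must be square")
  if (nrow(v) != length(object@labels))
    msgs <- c(msgs, "labels length must match matrix dimension")
  if (!all(is.finite(v))) msgs <- c(msgs, "non-finite dissimilarities")
  else {
    if (max(abs(v - t(v))) > 1e-8) msgs <- c(msgs, "matrix not symmetric")
    if (max(abs(diag(v))) > 1e-8) msgs <- c(msgs, "diagonal not zero")
  }
  if (length(msgs)) msgs else TRUE
})

#' PermutationResult: outcome of a randomization test
#'
#' @slot observed observed value of the test statistic.
#' @slot nullSample statistic values under the permutation null.
#' @slot p one-sided p-value, add-one convention
#'   \eqn{(1 + \#\{null \ge obs\})/(1 + n_{perm})}.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used.
#' @slot statistic short description of the statistic.
#' @aliases PermutationResult
#' @exportClass PermutationResult
setClass("PermutationResult",
  representation(observed = "numeric", nullSample = "numeric", p = "numeric",
                 nPerm = "integer", seed = "integer", statistic = "character"))

setValidity("PermutationResult", function(object) {
  msgs <- character(0)
  if (length(object@nullSample) != object@nPerm)
    msgs <- c(msgs, "length(nullSample) != nPerm")
  if (object@p <= 0 || object@p > 1) msgs <- c(msgs, "p must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' PairwiseChoiceSimilarity: similarity estimated from triplet choices
#'
#' Pairwise P(pair kept together) estimated from odd-one-out trials, with the
#' per-pair co-occurrence counts. Pairs that never co-occurred are flagged as
#' undefined (NA in \code{sim}), never silently zero.
#'
#' @slot labels object identifiers.
#' @slot sim symmetric matrix of choice probabilities in [0, 1], diagonal 1,
#'   NA where a pair never co-occurred.
#' @slot counts symmetric integer matrix of co-occurrence trial counts.
#' @aliases PairwiseChoiceSimilarity
#' @exportClass PairwiseChoiceSimilarity
setClass("PairwiseChoiceSimilarity",
  representation(labels = "character", sim = "matrix", counts = "matrix"))

setValidity("PairwiseChoiceSimilarity", function(object) {
  msgs <- character(0)
  n <- length(object@labels)
  if (!all(dim(object@sim) == n) || !all(dim(object@counts) == n))
    msgs <- c(msgs, "sim and counts must be n x n")
  s <- object@sim[is.finite(object@sim)]
  if (length(s) && (min(s) < -1e-12 || max(s) > 1 + 1e-12))
    msgs <- c(msgs, "similarities must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' DecodingResult: cross-validated classification outcome
#'
#' @slot meanAccuracy mean accuracy over iterations.
#' @slot standardError sd(per-iteration accuracies) / sqrt(n_iter).
#' @slot accuracies per-iteration accuracies.
#' @slot config echo of the \code{\link{decodeConfig}} used.
#' @slot nRedrawn number of candidate folds rejected because the training
#'   split lacked a class.
#' @aliases DecodingResult
#' @exportClass DecodingResult
setClass("DecodingResult",
  representation(meanAccuracy = "numeric", standardError = "numeric",
                 accuracies = "numeric", config = "list",
                 nRedrawn = "integer"))

#' MDSEmbedding: metric multidimensional scaling solution
#'
#' @slot labels point labels (stimulus identifiers).
#' @slot coordinates n x dims matrix of embedded coordinates.
#' @slot stress final raw stress \eqn{\sum_{i<j} (\delta_{ij} - d_{ij})^2}.
#' @aliases MDSEmbedding
#' @exportClass MDSEmbedding
setClass("MDSEmbedding",
  representation(labels = "character", coordinates = "matrix",
                 stress = "numeric"))

setValidity("MDSEmbedding", function(object) {
  msgs <- character(0)
  if (nrow(object@coordinates) != length(object@labels))
    msgs <- c(msgs, "coordinate rows must match labels")
  if (!all(is.finite(object@coordinates)))
    msgs <- c(msgs, "coordinates must be finite")
  if (object@stress < 0) msgs <- c(msgs, "stress must be nonnegative")
  if (length(msgs)) msgs else TRUE
})

#' TinyCNN: a small convolutional network
#'
#' Compact reference convolutional network (conv / ReLU / max-pool / fully
#' connected / softmax) used by the adapter operations: layerwise feature
#' extraction, and fine-tuning with a freeze boundary.
#'
#' @slot layers named list of layer descriptors in forward order. Each
#'   element is a list with a \code{type} field (\code{"conv"}, \code{"relu"},
#'   \code{"pool"}, \code{"flatten"}, \code{"fc"}) and, for parameterized
#'   layers, weight arrays.
#' @slot inputShape integer vector \code{c(channels, height, width)}.
#' @aliases TinyCNN
#' @exportClass TinyCNN
setClass("TinyCNN",
  representation(layers = "list", inputShape = "integer"))
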