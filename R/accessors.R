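#' Activation matrix of an ActivationSet
#'
#' @param x an \linkS4class{ActivationSet}.
#' @param ... unused.
#' @return the stimuli x features numeric matrix.
#' @rdname activations
#' @export
setMethod("activations", "ActivationSet", function(x, ...) x@activations)

#' Stimulus metadata table
#'
#' @param x an \linkS4class{ActivationSet} or
#'   \linkS4class{MultiLayerActivationSet}.
#' @param ... unused.
#' @return a \code{data.frame} with columns \code{object_id},
#'   \code{depiction}, \code{superordinate}.
#' @rdname stimulusMeta
#' @export
setMethod("stimulusMeta", "ActivationSet", function(x, ...) x@meta)

#' @rdname stimulusMeta
#' @export
setMethod("stimulusMeta", "MultiLayerActivationSet", function(x, ...) x@meta)

#' Layer names of a MultiLayerActivationSet
#'
#' @param x a \linkS4class{MultiLayerActivationSet}.
#' @return character vector of layer names in network order.
#' @rdname layerNames
#' @export
setMethod("layerNames", "MultiLayerActivationSet",
          function(x) names(x@layers))

#' @rdname layerNames
#' @export
setMethod("layerNames", "TinyCNN", function(x) names(x@layers))

#' Extract one layer as an ActivationSet
#'
#' @param x a \linkS4class{MultiLayerActivationSet}.
#' @param layer layer name.
#' @return an \linkS4class{ActivationSet} for that layer.
#' @rdname getLayer
#' @export
setMethod("getLayer", "MultiLayerActivationSet", function(x, layer) {
  if (!layer %in% names(x@layers))
    stop("unknown layer '", layer, "'; available: ",
         paste(names(x@layers), collapse = ", "))
  new("ActivationSet", activations = x@layers[[layer]], meta = x@meta)
})

#' Dissimilarity values of an RDM
#'
#' @param x an \linkS4class{RDM}.
#' @return square numeric matrix with \code{labels} as dimnames.
#' @rdname rdmValues
#' @export
setMethod("rdmValues", "RDM", function(x) {
  v <- x@values
  dimnames(v) <- list(x@labels, x@labels)
  v
})

#' Labels of an RDM
#'
#' @param x an \linkS4class{RDM} or \linkS4class{PairwiseChoiceSimilarity}.
#' @return character vector of stimulus labels.
#' @rdname rdmLabels
#' @export
setMethod("rdmLabels", "RDM", function(x) x@labels)

#' @rdname rdmLabels
#' @export
setMethod("rdmLabels", "PairwiseChoiceSimilarity", function(x) x@labels)

#' @rdname rdmLabels
#' @export
setMethod("rdmLabels", "MDSEmbedding", function(x) x@labels)

#' Null sample of a permutation test
#'
#' @param x a \linkS4class{PermutationResult}.
#' @return numeric vector of the statistic under the permutation null.
#' @rdname nullSample
#' @export
setMethod("nullSample", "PermutationResult", function(x) x@nullSample)

#' One-sided p-value of a permutation test
#'
#' @param x a \linkS4class{PermutationResult}.
#' @return the add-one one-sided p-value.
#' @rdname pValue
#' @export
setMethod("pValue", "PermutationResult", function(x) x@p)

#' Observed statistic of a permutation test
#'
#' @param x a \linkS4class{PermutationResult}.
#' @return the observed statistic.
#' @rdname observedStatistic
#' @export
setMethod("observedStatistic", "PermutationResult", function(x) x@observed)

#' Mean decoding accuracy
#'
#' @param x a \linkS4class{DecodingResult}.
#' @return mean accuracy across cross-validation iterations.
#' @rdname meanAccuracy
#' @export
setMethod("meanAccuracy", "DecodingResult", function(x) x@meanAccuracy)

#' Standard error of the decoding accuracy
#'
#' @param x a \linkS4class{DecodingResult}.
#' @return sd of per-iteration accuracies divided by sqrt(n_iter).
#' @rdname standardError
#' @export
setMethod("standardError", "DecodingResult", function(x) x@standardError)

#' Pairwise co-occurrence counts from triplet trials
#'
#' @param x a \linkS4class{PairwiseChoiceSimilarity}.
#' @return symmetric integer matrix of trial counts per pair.
#' @rdname choiceCounts
#' @export
setMethod("choiceCounts", "PairwiseChoiceSimilarity", function(x) {
  v <- x@counts
  dimnames(v) <- list(x@labels, x@labels)
  v
})

#' Pairwise choice-similarity matrix
#'
#' @param x a \linkS4class{PairwiseChoiceSimilarity}.
#' @return symmetric matrix of P(pair kept together); NA marks pairs that
#'   never co-occurred.
#' @rdname choiceSimilarity
#' @export
setMethod("choiceSimilarity", "PairwiseChoiceSimilarity", function(x) {
  v <- x@sim
  dimnames(v) <- list(x@labels, x@labels)
  v
})

setMethod("show", "ActivationSet", function(object) {
  cat(sprintf("ActivationSet: %d stimuli x %d features\n",
              nrow(object@activations), ncol(object@activations)))
  cat(" depictions:", paste(unique(object@meta$depiction), collapse = ", "),
      "\n")
})

setMethod("show", "MultiLayerActivationSet", function(object) {
  cat(sprintf("MultiLayerActivationSet: %d stimuli, %d layers\n",
              nrow(object@meta), length(object@layers)))
  for (nm in names(object@layers))
    cat(sprintf("  %s: %d features\n", nm, ncol(object@layers[[nm]])))
})

setMethod("show", "RDM", function(object) {
  n <- length(object@labels)
  v <- lowerTriangle(object)
  cat(sprintf("RDM: %d stimuli (%d pairwise dissimilarities)\n",
              n, length(v)))
  cat(sprintf("  range [%.4g, %.4g]\n", min(v), max(v)))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %s\n", object@statistic))
  cat(sprintf("  observed = %.6g, p = %.4g (one-sided, %d permutations, seed %d)\n",
              object@observed, object@p, object@nPerm, object@seed))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: mean accuracy %.4f (SE %.4f, %d iterations)\n",
              object@meanAccuracy, object@standardError,
              length(object@accuracies)))
})

setMethod("show", "PairwiseChoiceSimilarity", function(object) {
  n <- length(object@labels)
  undef <- sum(is.na(object@sim[upper.tri(object@sim)]))
  cat(sprintf("PairwiseChoiceSimilarity: %d objects, %d undefined pairs\n",
              n, undef))
})

setMethod("show", "MDSEmbedding", function(object) {
  cat(sprintf("MDSEmbedding: %d points in %d dims, raw stress %.6g\n",
              nrow(object@coordinates), ncol(object@coordinates),
              object@stress))
})

setMethod("show", "TinyCNN", function(object) {
  cat(sprintf("TinyCNN: input %s, layers: %s\n",
              paste(object@inputShape, collapse = "x"),
              paste(names(object@layers), collapse = " -> ")))
})
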