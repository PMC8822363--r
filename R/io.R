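#' Write / read a MultiLayerActivationSet as a directory of CSV files
#'
#' The container is a directory holding one CSV matrix per layer
#' (\code{layer_<n>_<name>.csv}, stimuli in rows), a sidecar
#' \code{metadata.csv} (object_id, depiction, superordinate) and a
#' \code{layers.txt} recording layer order.
#'
#' @param multi a \linkS4class{MultiLayerActivationSet}.
#' @param dir directory path (created if needed).
#' @return \code{writeActivations} returns \code{dir} invisibly;
#'   \code{readActivations} returns the reconstructed
#'   \linkS4class{MultiLayerActivationSet}.
#' @export
writeActivations <- function(multi, dir) {
  stopifnot(is(multi, "MultiLayerActivationSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- layerNames(multi)
  writeLines(nms, file.path(dir, "layers.txt"))
  utils::write.csv(multi@meta, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  for (k in seq_along(nms))
    utils::write.csv(as.data.frame(multi@layers[[k]]),
                     file.path(dir, sprintf("layer_%02d_%s.csv", k, nms[k])),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname writeActivations
#' @export
readActivations <- function(dir) {
  nms <- readLines(file.path(dir, "layers.txt"))
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE)
  layers <- list()
  for (k in seq_along(nms))
    layers[[nms[k]]] <- as.matrix(utils::read.csv(
      file.path(dir, sprintf("layer_%02d_%s.csv", k, nms[k]))))
  new("MultiLayerActivationSet", layers = layers, meta = meta)
}

#' Write / read triplet trials as CSV
#'
#' Columns: object_a, object_b, object_c, chosen.
#'
#' @param trials TripletDataset data.frame.
#' @param path CSV file path.
#' @export
writeTriplets <- function(trials, path) {
  utils::write.csv(trials[, c("object_a", "object_b", "object_c", "chosen")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTriplets
#' @export
readTriplets <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a choice-similarity estimate as a CSV pair
#'
#' Writes \code{<stem>_sim.csv} (probability matrix) and
#' \code{<stem>_counts.csv} (co-occurrence counts).
#'
#' @param x a \linkS4class{PairwiseChoiceSimilarity}.
#' @param stem path stem without extension.
#' @export
writeChoiceSimilarity <- function(x, stem) {
  stopifnot(is(x, "PairwiseChoiceSimilarity"))
  utils::write.csv(as.data.frame(choiceSimilarity(x)),
                   paste0(stem, "_sim.csv"), row.names = TRUE)
  utils::write.csv(as.data.frame(choiceCounts(x)),
                   paste0(stem, "_counts.csv"), row.names = TRUE)
  invisible(stem)
}
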