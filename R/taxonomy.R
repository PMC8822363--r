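#' Build a class taxonomy from an is-a edge list
#'
#' @param edges data.frame with columns \code{child}, \code{parent} (each row
#'   one is-a edge), or the path of a two-column TSV with that header.
#' @param indexMap optional named character vector mapping network output
#'   indices (names, as integers) to class identifiers; defaults to the node
#'   set in sorted order.
#' @return a list of class \code{TaxonomyGraph} with the \pkg{igraph} DAG
#'   (edges child -> parent) and the index mapping.
#' @export
taxonomyGraph <- function(edges, indexMap = NULL) {
  if (is.character(edges))
    edges <- utils::read.delim(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "parent") %in% colnames(edges)))
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) stop("taxonomy must be acyclic")
  nodes <- sort(igraph::V(g)$name)
  if (is.null(indexMap)) {
    indexMap <- nodes
    names(indexMap) <- as.character(seq_along(nodes))
  }
  structure(list(graph = g, indexMap = indexMap), class = "TaxonomyGraph")
}

#' Hyponym closure of a class
#'
#' All descendants (hyponyms) of \code{class}, excluding the class itself.
#'
#' @param taxonomy a \code{\link{taxonomyGraph}}.
#' @param class class identifier.
#' @return character vector of hyponym class identifiers (empty for leaves
#'   or for classes absent from the graph).
#' @export
hyponyms <- function(taxonomy, class) {
  g <- taxonomy$graph
  if (!class %in% igraph::V(g)$name) return(character(0))
  down <- igraph::subcomponent(g, class, mode = "in")$name
  setdiff(down, class)
}

#' Hierarchy-aware top-1 accuracy
#'
#' A prediction is counted correct if its class equals the target class or
#' lies anywhere in the target's hyponym (descendant) closure — e.g. with
#' dog -> {poodle, beagle}, predicting "poodle" for target "dog" is correct.
#' With an edgeless taxonomy this reduces to exact-match accuracy.
#'
#' @param predictedIndices integer vector of network output indices.
#' @param targets character vector of target class identifiers (same
#'   length); every target must be a taxonomy node or mapped class.
#' @param taxonomy a \code{\link{taxonomyGraph}} whose \code{indexMap}
#'   resolves every predicted index.
#' @return mean accuracy in [0, 1], with the per-item correctness vector in
#'   attribute \code{"correct"}.
#' @export
top1AccuracyHierarchy <- function(predictedIndices, targets, taxonomy) {
  stopifnot(length(predictedIndices) == length(targets))
  key <- as.character(predictedIndices)
  unmapped <- setdiff(key, names(taxonomy$indexMap))
  if (length(unmapped))
    stop("unmapped prediction index(es): ", paste(unmapped, collapse = ", "))
  pred_class <- unname(taxonomy$indexMap[key])
  known <- c(igraph::V(taxonomy$graph)$name, taxonomy$indexMap)
  missing_t <- setdiff(unique(targets), known)
  if (length(missing_t))
    stop("target class(es) missing from taxonomy: ",
         paste(missing_t, collapse = ", "))
  correct <- vapply(seq_along(targets), function(i) {
    pred_class[i] == targets[i] ||
      pred_class[i] %in% hyponyms(taxonomy, targets[i])
  }, logical(1))
  acc <- mean(correct)
  attr(acc, "correct") <- correct
  acc
}
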