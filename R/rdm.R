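#' Construct an RDM from a dissimilarity matrix
#'
#' Low-level constructor; most users will call \code{\link{computeRDM}}.
#' The matrix is symmetrized (average of the matrix and its transpose) when
#' the asymmetry is within \code{tol}, and the diagonal is forced to zero.
#'
#' @param values square numeric matrix of dissimilarities.
#' @param labels stimulus identifiers; defaults to the matrix row names.
#' @param tol maximum tolerated asymmetry / diagonal deviation.
#' @return an \linkS4class{RDM}.
#' @export
rdm <- function(values, labels = rownames(values), tol = 1e-8) {
  if (!is.matrix(values) || nrow(values) != ncol(values))
    stop("values must be a square matrix")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  if (!all(is.finite(values))) stop("dissimilarities must be finite")
  if (max(abs(values - t(values))) > tol)
    stop("dissimilarity matrix is asymmetric beyond tolerance")
  if (max(abs(diag(values))) > tol)
    stop("dissimilarity diagonal deviates from zero beyond tolerance")
  v <- (values + t(values)) / 2
  diag(v) <- 0
  dimnames(v) <- NULL
  new("RDM", labels = as.character(labels), values = v)
}

#' Compute a correlation-distance RDM from activation patterns
#'
#' Pairwise dissimilarity between stimulus response patterns is the
#' correlation distance \eqn{d(i,j) = 1 - r_{ij}} where \eqn{r_{ij}} is the
#' Pearson correlation of activation rows i and j. Entries lie in [0, 2];
#' the diagonal is exactly zero.
#'
#' @param acts an \linkS4class{ActivationSet}, or a plain numeric matrix with
#'   stimuli in rows (row names become labels).
#' @return an \linkS4class{RDM} labeled by \code{object_id} (for an
#'   \code{ActivationSet}) or row names.
#' @details A stimulus row with zero variance has no defined correlation with
#'   anything; such rows raise an error naming the offending stimulus rather
#'   than being dropped, so that labels stay aligned across depictions.
#' @examples
#' x <- matrix(rnorm(20), 4, 5, dimnames = list(letters[1:4], NULL))
#' computeRDM(x)
#' @export
computeRDM <- function(acts) {
  if (is(acts, "ActivationSet")) {
    x <- acts@activations
    labels <- acts@meta$object_id
  } else if (is.matrix(acts)) {
    x <- acts
    labels <- rownames(x) %||% as.character(seq_len(nrow(x)))
  } else stop("acts must be an ActivationSet or a matrix")
  if (nrow(x) < 3) stop("need at least 3 stimuli")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance activation pattern for stimulus: ",
         paste(labels[sds == 0], collapse = ", "),
         " (Pearson correlation undefined)")
  d <- 1 - stats::cor(t(x))
  d <- pmin(pmax(d, 0), 2)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- NULL
  new("RDM", labels = as.character(labels), values = d)
}

#' Super-RDM over all depiction types of a layer
#'
#' One RDM over every stimulus (all objects x all depiction types) of a given
#' layer, so that within- and cross-depiction dissimilarity blocks can be
#' inspected jointly (and embedded with \code{\link{mdsEmbed}}). Labels are
#' \code{"<object_id>|<depiction>"}.
#'
#' @param multi a \linkS4class{MultiLayerActivationSet}.
#' @param layer layer name.
#' @param depictions depiction types that must all be present (default: every
#'   depiction in the metadata).
#' @return an \linkS4class{RDM} of size (n_objects * n_depictions)^2; its
#'   within-depiction diagonal blocks equal \code{computeRDM} on the
#'   corresponding subset exactly.
#' @export
superRDM <- function(multi, layer, depictions = NULL) {
  stopifnot(is(multi, "MultiLayerActivationSet"))
  as <- getLayer(multi, layer)
  m <- as@meta
  if (is.null(depictions)) depictions <- unique(m$depiction)
  missing_dep <- setdiff(depictions, unique(m$depiction))
  if (length(missing_dep))
    stop("missing depiction rows for: ", paste(missing_dep, collapse = ", "))
  keep <- m$depiction %in% depictions
  ord <- order(match(m$depiction[keep], depictions))
  idx <- which(keep)[ord]
  x <- as@activations[idx, , drop = FALSE]
  rownames(x) <- paste(m$object_id[idx], m$depiction[idx], sep = "|")
  computeRDM(x)
}

#' Split an ActivationSet by depiction type
#'
#' @param acts an \linkS4class{ActivationSet}.
#' @return named list of \linkS4class{ActivationSet}s, one per depiction,
#'   each ordered by \code{object_id}.
#' @export
splitByDepiction <- function(acts) {
  stopifnot(is(acts, "ActivationSet"))
  m <- acts@meta
  out <- list()
  for (d in unique(m$depiction)) {
    idx <- which(m$depiction == d)
    idx <- idx[order(m$object_id[idx])]
    out[[d]] <- new("ActivationSet",
                    activations = acts@activations[idx, , drop = FALSE],
                    meta = m[idx, , drop = FALSE])
  }
  out
}

#' Lower-triangle vector of an RDM
#'
#' Extracts the strictly-below-diagonal entries in a fixed documented order:
#' row-major by increasing row index, columns left of the diagonal — i.e. for
#' 4 objects, (d21, d31, d32, d41, d42, d43). The label order that produced
#' the vector travels with it as the \code{"labels"} attribute.
#'
#' @param x an \linkS4class{RDM} or a square symmetric matrix.
#' @param ... unused.
#' @return numeric vector of length n(n-1)/2 with attribute \code{labels}.
#' @rdname lowerTriangle
#' @export
setMethod("lowerTriangle", "RDM", function(x, ...) {
  v <- t(x@values)[upper.tri(x@values)]
  attr(v, "labels") <- x@labels
  v
})

#' @rdname lowerTriangle
#' @export
setMethod("lowerTriangle", "matrix", function(x, tol = 1e-8, ...) {
  if (nrow(x) != ncol(x) || max(abs(x - t(x))) > tol)
    stop("input is not symmetric within tolerance")
  v <- t(x)[upper.tri(x)]
  attr(v, "labels") <- rownames(x)
  v
})

#' Pixel-based RDM from images
#'
#' Preprocesses each image (see \code{\link{preprocessImage}}), flattens the
#' resulting arrays and computes the correlation-distance RDM, giving the
#' baseline "raw pixel" representational geometry.
#'
#' @param images list of images (arrays, or PNG file paths).
#' @param config a \code{\link{preprocessConfig}}.
#' @param labels stimulus labels; defaults to list names or indices.
#' @return an \linkS4class{RDM}.
#' @export
pixelRDM <- function(images, config = preprocessConfig(), labels = NULL) {
  if (!length(images)) stop("no images supplied")
  proc <- lapply(images, preprocessImage, config = config)
  lens <- vapply(proc, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("mismatched image sizes after preprocessing")
  x <- do.call(rbind, lapply(proc, as.vector))
  rownames(x) <- labels %||% names(images) %||%
    as.character(seq_len(nrow(x)))
  computeRDM(x)
}

#' Write / read an RDM as labeled CSV
#'
#' @param x an \linkS4class{RDM}.
#' @param path CSV file path.
#' @return \code{writeRDM} returns \code{path} invisibly; \code{readRDM}
#'   returns an \linkS4class{RDM}.
#' @export
writeRDM <- function(x, path) {
  stopifnot(is(x, "RDM"))
  utils::write.csv(as.data.frame(rdmValues(x)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname writeRDM
#' @export
readRDM <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  rdm(as.matrix(df), labels = rownames(df))
}

#' Heatmap of an RDM
#'
#' Writes a PNG heatmap of the dissimilarity matrix (base graphics).
#'
#' @param x an \linkS4class{RDM}.
#' @param path output PNG path.
#' @param main plot title.
#' @export
plotRDM <- function(x, path, main = "RDM") {
  stopifnot(is(x, "RDM"))
  v <- x@values
  grDevices::png(path, width = 600, height = 600)
  on.exit(grDevices::dev.off())
  n <- nrow(v)
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "", ylab = "", axes = FALSE, main = main)
  invisible(path)
}
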