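#' Spearman correlation between two RDMs
#'
#' The similarity of two representational geometries is measured as the
#' Spearman rank correlation between the lower-triangle vectors of the two
#' RDMs. RDMs are aligned by label (never by position) before extraction;
#' ties receive average ranks.
#'
#' @param a,b \linkS4class{RDM}s over the same label set (any order).
#' @return Spearman rho in [-1, 1]; \code{NA} (with a warning) if either
#'   lower triangle is constant, in which case the rank correlation is
#'   undefined.
#' @export
rdmSpearman <- function(a, b) {
  stopifnot(is(a, "RDM"), is(b, "RDM"))
  b <- alignRDM(b, a@labels)
  va <- lowerTriangle(a)
  vb <- lowerTriangle(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("constant lower triangle: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb, method = "spearman")
}

#' Reorder an RDM to a target label order
#'
#' @param x an \linkS4class{RDM}.
#' @param labels target label order; must be a permutation of
#'   \code{rdmLabels(x)}.
#' @return the relabeled \linkS4class{RDM}.
#' @export
alignRDM <- function(x, labels) {
  stopifnot(is(x, "RDM"))
  if (!setequal(x@labels, labels) || length(x@labels) != length(labels)) {
    only_x <- setdiff(x@labels, labels)
    only_t <- setdiff(labels, x@labels)
    stop("RDM label mismatch; only in RDM: {",
         paste(only_x, collapse = ", "), "}; only in target: {",
         paste(only_t, collapse = ", "), "}")
  }
  idx <- match(labels, x@labels)
  new("RDM", labels = x@labels[idx],
      values = x@values[idx, idx, drop = FALSE])
}

#' Cross-depiction RDM correlation profile
#'
#' For every layer, computes one RDM per depiction type and the Spearman
#' correlation between each pair of depiction RDMs (e.g. photo-to-drawing,
#' photo-to-sketch, drawing-to-sketch similarity). The layerwise profile of
#' these correlations is the central measure of how well representational
#' geometry generalizes across levels of visual abstraction.
#'
#' @param multi a \linkS4class{MultiLayerActivationSet} containing every
#'   depiction in every layer.
#' @param depictions depiction order; defaults to order of appearance.
#' @return a \code{data.frame} with columns \code{layer}, \code{pair},
#'   \code{rho}; layers in network order.
#' @export
crossDepictionProfile <- function(multi, depictions = NULL) {
  stopifnot(is(multi, "MultiLayerActivationSet"))
  if (is.null(depictions)) depictions <- unique(multi@meta$depiction)
  if (length(depictions) < 2) stop("need at least two depiction types")
  pairs <- utils::combn(depictions, 2)
  out <- list()
  for (layer in layerNames(multi)) {
    rdms <- lapply(splitByDepiction(getLayer(multi, layer)), computeRDM)
    miss <- setdiff(depictions, names(rdms))
    if (length(miss))
      stop("layer '", layer, "' missing depictions: ",
           paste(miss, collapse = ", "))
    for (k in seq_len(ncol(pairs))) {
      d1 <- pairs[1, k]; d2 <- pairs[2, k]
      out[[length(out) + 1]] <- data.frame(
        layer = layer, pair = paste(d1, d2, sep = "-"),
        rho = rdmSpearman(rdms[[d1]], rdms[[d2]]))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-depiction RDMs for every layer
#'
#' @param multi a \linkS4class{MultiLayerActivationSet}.
#' @return nested list: \code{[[layer]][[depiction]]} -> \linkS4class{RDM}.
#' @export
layerDepictionRDMs <- function(multi) {
  stopifnot(is(multi, "MultiLayerActivationSet"))
  out <- list()
  for (layer in layerNames(multi))
    out[[layer]] <- lapply(splitByDepiction(getLayer(multi, layer)),
                           computeRDM)
  out
}

#' Metric multidimensional scaling of an RDM
#'
#' Embeds the stimuli in \code{dims} dimensions by minimizing the raw metric
#' stress \eqn{\sum_{i<j} (\delta_{ij} - d_{ij})^2} with SMACOF majorization
#' (Guttman transform). The first initialization is the classical-scaling
#' solution; the remaining \code{nRestarts - 1} are random configurations
#' drawn under \code{seed}, and the lowest-stress solution is returned.
#'
#' @param x an \linkS4class{RDM}.
#' @param dims embedding dimensionality (default 2).
#' @param seed RNG seed for the random restarts.
#' @param nRestarts number of initializations (>= 1).
#' @param maxIter majorization iterations per restart.
#' @param tol relative stress-decrease convergence threshold.
#' @return an \linkS4class{MDSEmbedding} with coordinates and final raw
#'   stress.
#' @export
mdsEmbed <- function(x, dims = 2, seed = 1, nRestarts = 8, maxIter = 500,
                     tol = 1e-10) {
  stopifnot(is(x, "RDM"), dims >= 1, nRestarts >= 1)
  delta <- x@values
  if (!all(is.finite(delta))) stop("non-finite distances")
  n <- nrow(delta)
  scale0 <- mean(delta[upper.tri(delta)])
  if (!is.finite(scale0) || scale0 <= 0) scale0 <- 1

  inits <- with_seed(seed, {
    ini <- list(classical_init(delta, dims))
    for (r in seq_len(max(0, nRestarts - 1)))
      ini[[r + 1]] <- matrix(stats::rnorm(n * dims, sd = scale0), n, dims)
    ini
  })

  best <- NULL
  for (X0 in inits) {
    fit <- smacof_raw(delta, X0, maxIter, tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  new("MDSEmbedding", labels = x@labels, coordinates = best$X,
      stress = best$stress)
}

classical_init <- function(delta, dims) {
  cs <- suppressWarnings(stats::cmdscale(delta, k = dims))
  if (ncol(cs) < dims)
    cs <- cbind(cs, matrix(0, nrow(delta), dims - ncol(cs)))
  # tiny jitter avoids coincident points (zero distances stall the transform)
  cs + matrix(stats::rnorm(length(cs), sd = 1e-8), nrow(cs), ncol(cs))
}

raw_stress <- function(delta, X) {
  d <- as.matrix(stats::dist(X))
  sum((delta[upper.tri(delta)] - d[upper.tri(d)])^2)
}

smacof_raw <- function(delta, X, maxIter, tol) {
  n <- nrow(delta)
  s_old <- raw_stress(delta, X)
  for (it in seq_len(maxIter)) {
    d <- as.matrix(stats::dist(X))
    ratio <- ifelse(d > 1e-12, delta / d, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- (B %*% X) / n
    s_new <- raw_stress(delta, X)
    if (s_old - s_new < tol * max(s_old, .Machine$double.eps)) {
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  list(X = X, stress = s_old)
}

#' Scatter plot of an MDS embedding
#'
#' Writes a PNG of the first two embedding dimensions with depiction-coded
#' markers (labels of the form \code{"object|depiction"} are split on
#' \code{"|"}).
#'
#' @param emb an \linkS4class{MDSEmbedding}.
#' @param path output PNG path.
#' @export
plotMDS <- function(emb, path) {
  stopifnot(is(emb, "MDSEmbedding"))
  parts <- strsplit(emb@labels, "|", fixed = TRUE)
  dep <- vapply(parts, function(p) if (length(p) > 1) p[2] else "all",
                character(1))
  depf <- factor(dep)
  grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  graphics::plot(emb@coordinates[, 1], emb@coordinates[, 2],
                 col = as.integer(depf), pch = as.integer(depf),
                 xlab = "MDS 1", ylab = "MDS 2",
                 main = sprintf("metric MDS (raw stress %.3g)", emb@stress))
  graphics::legend("topright", legend = levels(depf),
                   col = seq_along(levels(depf)), pch = seq_along(levels(depf)))
  invisible(path)
}
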