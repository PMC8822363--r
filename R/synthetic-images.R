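#' Generate synthetic photo-like / drawing-like image pairs
#'
#' For each object a random polygon is rendered twice on a gray canvas: a
#' filled, speckle-textured variant (photo-like) and a contour-only variant
#' (drawing-like) of the exact same polygon. These synthetic stimuli exercise
#' the image preprocessing, pixel-RDM and network-adapter paths; they make no
#' claim to photorealism.
#'
#' @param nObjects number of objects (>= 2).
#' @param canvas square canvas side in pixels (>= 16).
#' @param nVertices polygon vertex count (default 8).
#' @param background gray level of the background in [0, 1] (default 0.5).
#' @param seed RNG seed; different seeds give different vertex sets.
#' @return list with \code{images} (named list of canvas x canvas x 3 arrays
#'   in [0, 1], names \code{"<object_id>|<depiction>"}), \code{metadata}
#'   (data.frame object_id / depiction / superordinate) and \code{polygons}
#'   (per-object vertex matrices, shared exactly by the two variants).
#' @export
generateImages <- function(nObjects = 8, canvas = 64, nVertices = 8,
                           background = 0.5, seed = 1) {
  if (nObjects < 2) stop("need at least 2 objects")
  if (canvas < 16) stop("degenerate canvas size (need >= 16 pixels)")
  with_seed(seed, {
    ids <- sprintf("obj%03d", seq_len(nObjects))
    sup <- rep(c("manmade", "natural"), length.out = nObjects)
    images <- list()
    polys <- list()
    for (o in seq_len(nObjects)) {
      ang <- sort(stats::runif(nVertices, 0, 2 * pi))
      rad <- stats::runif(nVertices, 0.22, 0.42) * canvas
      cx <- canvas / 2 + stats::runif(1, -0.05, 0.05) * canvas
      cy <- canvas / 2 + stats::runif(1, -0.05, 0.05) * canvas
      poly <- cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
      polys[[ids[o]]] <- poly
      # fills are uniformly darker than the gray background, mimicking the
      # shared first-order statistics of photographed objects; the contour
      # variant keeps only the polygon outline
      base_col <- stats::runif(3, 0.05, 0.35)
      mask <- polygon_mask(poly, canvas)
      photo <- array(background, dim = c(canvas, canvas, 3))
      speck <- matrix(stats::runif(canvas * canvas, -0.12, 0.12),
                      canvas, canvas)
      for (ch in 1:3) {
        plane <- photo[, , ch]
        plane[mask] <- pmin(pmax(base_col[ch] + speck[mask], 0), 1)
        photo[, , ch] <- plane
      }
      # contours are drawn brighter than the background while fills are
      # darker, so the two rendering styles occupy opposite pixel-intensity
      # regimes (as photographs and line drawings do relative to their
      # low-level statistics)
      contour <- array(background, dim = c(canvas, canvas, 3))
      edge <- polygon_outline(poly, canvas)
      for (ch in 1:3) {
        plane <- contour[, , ch]
        plane[edge] <- 0.95
        contour[, , ch] <- plane
      }
      images[[paste0(ids[o], "|photo")]] <- photo
      images[[paste0(ids[o], "|drawing")]] <- contour
    }
    metadata <- data.frame(
      object_id = rep(ids, each = 2),
      depiction = rep(c("photo", "drawing"), times = nObjects),
      superordinate = rep(sup, each = 2), stringsAsFactors = FALSE)
    list(images = images, metadata = metadata, polygons = polys)
  })
}

# Even-odd scanline rasterization; returns a logical canvas x canvas matrix
# (row = y, column = x, pixel centers at integer + 0.5).
polygon_mask <- function(poly, canvas) {
  n <- nrow(poly)
  mask <- matrix(FALSE, canvas, canvas)
  xs <- poly[, 1]; ys <- poly[, 2]
  for (row in seq_len(canvas)) {
    y <- row - 0.5
    crossings <- numeric(0)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      y1 <- ys[k]; y2 <- ys[k2]
      if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
        t <- (y - y1) / (y2 - y1)
        crossings <- c(crossings, xs[k] + t * (xs[k2] - xs[k]))
      }
    }
    crossings <- sort(crossings)
    if (length(crossings) >= 2)
      for (k in seq(1, length(crossings) - 1, by = 2)) {
        lo <- max(1L, ceiling(crossings[k] + 0.5))
        hi <- min(canvas, floor(crossings[k + 1] + 0.5))
        if (lo <= hi) mask[row, lo:hi] <- TRUE
      }
  }
  mask
}

# Mark pixels along the polygon edges by dense parametric sampling.
polygon_outline <- function(poly, canvas) {
  n <- nrow(poly)
  edge <- matrix(FALSE, canvas, canvas)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    len <- sqrt(sum((poly[k2, ] - poly[k, ])^2))
    m <- max(2L, ceiling(len * 3))
    t <- seq(0, 1, length.out = m)
    px <- round(poly[k, 1] + t * (poly[k2, 1] - poly[k, 1]) + 0.5)
    py <- round(poly[k, 2] + t * (poly[k2, 2] - poly[k, 2]) + 0.5)
    ok <- px >= 1 & px <= canvas & py >= 1 & py <= canvas
    edge[cbind(py[ok], px[ok])] <- TRUE
  }
  edge
}

#' Write a set of generated images as PNG files
#'
#' @param imageSet result of \code{\link{generateImages}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeImages <- function(imageSet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(imageSet$images)) {
    fn <- file.path(dir, paste0(gsub("|", "_", nm, fixed = TRUE), ".png"))
    png::writePNG(imageSet$images[[nm]], fn)
    paths <- c(paths, fn)
  }
  utils::write.csv(imageSet$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(paths)
}
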