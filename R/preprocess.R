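#' Image preprocessing configuration
#'
#' Controls how stimulus images are standardized before pixel-RDM computation
#' or network feature extraction: the object is scaled to fit, centered on a
#' square gray canvas, resized to \code{canvas x canvas} and channel-
#' normalized. The normalization constants default to the canonical
#' per-channel natural-image statistics but are configuration data, since
#' "zero mean, unit variance" is ambiguous between per-image and dataset
#' statistics.
#'
#' @param canvas square side in pixels (default 224, >= 32).
#' @param background gray level of the canvas in [0, 1] (default 0.5).
#' @param margin fraction of the canvas kept free around the object
#'   (default 0.05).
#' @param means,sds length-3 per-channel normalization constants.
#' @param backgroundTol absolute tolerance when detecting background-colored
#'   pixels (used when no alpha channel is present).
#' @return a list of class \code{PreprocessConfig}.
#' @export
preprocessConfig <- function(canvas = 224, background = 0.5, margin = 0.05,
                             means = c(0.485, 0.456, 0.406),
                             sds = c(0.229, 0.224, 0.225),
                             backgroundTol = 0.02) {
  if (canvas < 32) stop("canvas must be at least 32 pixels")
  if (length(means) != 3 || length(sds) != 3)
    stop("normalization vectors must have length 3")
  if (any(sds <= 0)) stop("normalization sds must be positive")
  structure(list(canvas = as.integer(canvas), background = background,
                 margin = margin, means = means, sds = sds,
                 backgroundTol = backgroundTol),
            class = "PreprocessConfig")
}

#' Preprocess a stimulus image
#'
#' Detects the foreground (alpha channel when present, otherwise a
#' background-color mask), crops to its bounding box, scales it preserving
#' aspect ratio to fit the canvas minus margin, centers it on a gray canvas
#' and normalizes each channel as (x - mean) / sd. Deterministic.
#'
#' @param image a PNG file path, or a numeric array: H x W (gray),
#'   H x W x 3 (RGB) or H x W x 4 (RGBA), values in [0, 1].
#' @param config a \code{\link{preprocessConfig}}.
#' @return canvas x canvas x 3 normalized numeric array, with the foreground
#'   detection mode recorded in attribute \code{"foreground"}.
#' @export
preprocessImage <- function(image, config = preprocessConfig()) {
  if (is.character(image)) {
    if (!file.exists(image)) stop("unreadable image: ", image)
    arr <- tryCatch(png::readPNG(image),
                    error = function(e) stop("unreadable image: ", image,
                                             " (", conditionMessage(e), ")"))
  } else arr <- image
  if (is.matrix(arr)) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (length(dim(arr)) != 3 || !all(dim(arr)[1:2] >= 1) ||
      any(dim(arr)[1:2] == 0))
    stop("image must be a nonempty 2-D or 3-D array")

  if (dim(arr)[3] >= 4) {
    mask <- arr[, , 4] > 0.5
    rgb <- arr[, , 1:3, drop = FALSE]
    fg_mode <- "alpha"
  } else {
    rgb <- arr[, , 1:3, drop = FALSE]
    dev <- sqrt((rgb[, , 1] - config$background)^2 +
                (rgb[, , 2] - config$background)^2 +
                (rgb[, , 3] - config$background)^2)
    mask <- dev > config$backgroundTol
    fg_mode <- "background-mask"
  }

  cv <- config$canvas
  canvas <- array(config$background, dim = c(cv, cv, 3))
  if (any(mask)) {
    rows <- range(which(apply(mask, 1, any)))
    cols <- range(which(apply(mask, 2, any)))
    crop <- rgb[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
    bh <- dim(crop)[1]; bw <- dim(crop)[2]
    target <- cv * (1 - 2 * config$margin)
    s <- min(target / bh, target / bw)
    nh <- max(1L, round(bh * s)); nw <- max(1L, round(bw * s))
    # EBImage treats dim 1 as width; pass sizes positionally for dim1, dim2
    scaled <- EBImage::resize(crop, w = nh, h = nw)
    scaled <- pmin(pmax(scaled, 0), 1)
    r0 <- floor((cv - nh) / 2)
    c0 <- floor((cv - nw) / 2)
    canvas[(r0 + 1):(r0 + nh), (c0 + 1):(c0 + nw), ] <- scaled
  }
  for (ch in 1:3)
    canvas[, , ch] <- (canvas[, , ch] - config$means[ch]) / config$sds[ch]
  attr(canvas, "foreground") <- fg_mode
  canvas
}
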