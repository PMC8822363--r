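#' Configuration for the synthetic activation generator
#'
#' The generator plants a known latent structure so that every downstream
#' stage (RDM comparison, decoding, inference) can be verified by parameter
#' recovery. Each object o has a shared latent z_o common to all depiction
#' types and an independent idiosyncratic latent u_{o,d} per depiction d. The
#' pre-map representation of stimulus (o, d) in layer l is
#' \deqn{\alpha_l z_o + \sqrt{1 - \alpha_l^2}\, u_{o,d},}
#' so the per-layer shared fraction \eqn{\alpha_l \in [0,1]} is the sole
#' driver of cross-depiction representational similarity: the expected
#' cross-depiction RDM correlation increases monotonically in \eqn{\alpha_l}.
#' A class direction scaled by \code{classSignal} is added with opposite sign
#' for manmade vs. natural objects — to the shared latent
#' (\code{classSignalMode = "shared"}, decodable across depictions) or to
#' each depiction's idiosyncratic latent along depiction-specific directions
#' (\code{classSignalMode = "depiction"}, decodable only within a depiction).
#'
#' @param nObjects number of object categories (default 42).
#' @param nManmade number of manmade objects (default 21); the remainder are
#'   natural.
#' @param depictions ordered depiction type names (default photo, drawing,
#'   sketch).
#' @param layers named numeric vector: feature dimensionality per layer.
#' @param sharedFraction per-layer \eqn{\alpha_l} in [0, 1]; recycled to the
#'   number of layers.
#' @param latentDim latent dimensionality (default 12).
#' @param noiseSd additive Gaussian measurement noise sd (default 0.1).
#' @param classSignal strength of the manmade/natural latent direction
#'   (default 0).
#' @param classSignalMode \code{"shared"} or \code{"depiction"} (see above).
#' @param seed integer RNG seed.
#' @return a validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(nObjects = 42, nManmade = 21,
                            depictions = c("photo", "drawing", "sketch"),
                            layers = c(pool1 = 64, pool2 = 64, pool3 = 64,
                                       pool4 = 64, fc1 = 64),
                            sharedFraction = c(0.3, 0.6, 0.9, 0.6, 0.3),
                            latentDim = 12, noiseSd = 0.1, classSignal = 0,
                            classSignalMode = c("shared", "depiction"),
                            seed = 1) {
  classSignalMode <- match.arg(classSignalMode)
  sharedFraction <- rep_len(sharedFraction, length(layers))
  cfg <- list(nObjects = as.integer(nObjects),
              nManmade = as.integer(nManmade),
              depictions = as.character(depictions),
              layers = layers, sharedFraction = sharedFraction,
              latentDim = as.integer(latentDim), noiseSd = noiseSd,
              classSignal = classSignal, classSignalMode = classSignalMode,
              seed = check_seed(seed))
  class(cfg) <- "SyntheticConfig"
  validateSyntheticConfig(cfg)
  cfg
}

validateSyntheticConfig <- function(cfg) {
  if (any(cfg$sharedFraction < 0 | cfg$sharedFraction > 1))
    stop("configuration error: shared fraction alpha must lie in [0, 1]")
  if (cfg$nManmade > cfg$nObjects)
    stop("configuration error: nManmade must not exceed nObjects")
  if (cfg$nObjects < 2 || cfg$latentDim < 2 || any(cfg$layers < 2))
    stop("configuration error: all dimensionalities must be >= 2")
  if (cfg$noiseSd < 0)
    stop("configuration error: noiseSd must be nonnegative")
  if (is.null(names(cfg$layers)) || any(names(cfg$layers) == ""))
    stop("configuration error: layers must be named")
  invisible(cfg)
}

#' Stimulus metadata table for a synthetic configuration
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return data.frame with one row per stimulus (object x depiction), columns
#'   \code{object_id}, \code{depiction}, \code{superordinate}; every object
#'   appears once per depiction, rows grouped by depiction.
#' @export
syntheticMetadata <- function(cfg) {
  ids <- sprintf("obj%03d", seq_len(cfg$nObjects))
  sup <- c(rep("manmade", cfg$nManmade),
           rep("natural", cfg$nObjects - cfg$nManmade))
  data.frame(
    object_id = rep(ids, times = length(cfg$depictions)),
    depiction = rep(cfg$depictions, each = cfg$nObjects),
    superordinate = rep(sup, times = length(cfg$depictions)),
    stringsAsFactors = FALSE)
}

#' Generate multi-layer activations with planted cross-depiction structure
#'
#' Draws the latent model described in \code{\link{syntheticConfig}} and maps
#' it into each layer's feature space through one random linear map per layer
#' shared across depictions (mirroring shared network weights across inputs),
#' plus additive Gaussian noise. Bit-reproducible given the config seed.
#'
#' @param cfg a \code{\link{syntheticConfig}}.
#' @return a \linkS4class{MultiLayerActivationSet}. The planted object
#'   similarity implied by the shared latents (1 minus the correlation
#'   distance of the z_o) is attached as attribute
#'   \code{"plantedSimilarity"} for recovery checks.
#' @export
generateActivations <- function(cfg) {
  validateSyntheticConfig(cfg)
  meta <- syntheticMetadata(cfg)
  nO <- cfg$nObjects
  nD <- length(cfg$depictions)
  L <- cfg$latentDim
  with_seed(cfg$seed, {
    z <- matrix(stats::rnorm(nO * L), nO, L)
    sgn <- ifelse(meta$superordinate[seq_len(nO)] == "manmade", 1, -1)
    v <- stats::rnorm(L)
    v <- v / sqrt(sum(v^2))
    # depiction-specific class directions are mutually orthogonal, so a class
    # code carried by them cannot transfer across depictions by construction
    vd_raw <- matrix(stats::rnorm(L * nD), L, nD)
    vd_q <- qr.Q(qr(vd_raw))
    vdep <- lapply(seq_len(nD), function(d) vd_q[, d])
    if (cfg$classSignal > 0 && cfg$classSignalMode == "shared")
      z <- z + cfg$classSignal * outer(sgn, v)
    u <- lapply(seq_len(nD), function(d) {
      ud <- matrix(stats::rnorm(nO * L), nO, L)
      if (cfg$classSignal > 0 && cfg$classSignalMode == "depiction")
        ud <- ud + cfg$classSignal * outer(sgn, vdep[[d]])
      ud
    })
    layers <- list()
    for (li in seq_along(cfg$layers)) {
      p <- cfg$layers[[li]]
      a <- cfg$sharedFraction[[li]]
      A <- matrix(stats::rnorm(p * L, sd = 1 / sqrt(L)), L, p)
      rows <- vector("list", nD)
      for (d in seq_len(nD)) {
        latent <- a * z + sqrt(1 - a^2) * u[[d]]
        x <- latent %*% A
        if (cfg$noiseSd > 0)
          x <- x + matrix(stats::rnorm(length(x), sd = cfg$noiseSd),
                          nrow(x), ncol(x))
        rows[[d]] <- x
      }
      layers[[names(cfg$layers)[li]]] <- do.call(rbind, rows)
    }
    planted <- 1 - (1 - stats::cor(t(z)))  # = cor(t(z)); kept explicit
    dimnames(planted) <- list(sprintf("obj%03d", seq_len(nO)),
                              sprintf("obj%03d", seq_len(nO)))
    out <- new("MultiLayerActivationSet", layers = layers, meta = meta)
    attr(out, "plantedSimilarity") <- planted
    out
  })
}

#' Simulate triplet odd-one-out trials from a known similarity matrix
#'
#' For each trial three distinct objects are shown and the simulated chooser
#' picks the odd one out: the object i minimizing sim(i, j) + sim(i, k) over
#' the triplet. The deterministic model breaks ties uniformly at random under
#' the trial's seed stream; the softmax model samples choice i with
#' probability proportional to exp(-(sim(i,j) + sim(i,k)) / temperature).
#'
#' @param similarity symmetric similarity matrix with unit diagonal; dimnames
#'   give object ids (defaults to \code{obj001...}).
#' @param mode \code{"exhaustive"} (every unordered triple once, C(n,3)
#'   trials) or \code{"sampled"} (\code{nTrials} uniform random triples).
#' @param nTrials number of trials in sampled mode.
#' @param choiceModel \code{"deterministic"} or \code{"softmax"}.
#' @param temperature softmax temperature (> 0).
#' @param seed RNG seed.
#' @return data.frame with columns \code{object_a}, \code{object_b},
#'   \code{object_c}, \code{chosen} (a TripletDataset).
#' @export
generateTripletTrials <- function(similarity, mode = c("exhaustive",
                                                       "sampled"),
                                  nTrials = NULL,
                                  choiceModel = c("deterministic", "softmax"),
                                  temperature = 0.1, seed = 1) {
  mode <- match.arg(mode)
  choiceModel <- match.arg(choiceModel)
  S <- as.matrix(similarity)
  n <- nrow(S)
  if (n < 3) stop("need at least 3 objects for triplet trials")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity must be symmetric")
  if (max(abs(diag(S) - 1)) > 1e-8) stop("similarity must have unit diagonal")
  ids <- rownames(S) %||% sprintf("obj%03d", seq_len(n))
  if (mode == "exhaustive") {
    triples <- t(utils::combn(n, 3))
  } else {
    if (is.null(nTrials) || nTrials < 1) stop("sampled mode requires nTrials")
    triples <- with_seed(derive_seed(seed, 1), {
      t(replicate(nTrials, sample.int(n, 3)))
    })
  }
  if (temperature <= 0) stop("temperature must be positive")
  chosen <- with_seed(derive_seed(seed, 2), {
    apply(triples, 1, function(tr) {
      # score_i = summed similarity of i to the other two; odd one out
      # minimizes it
      sc <- c(S[tr[1], tr[2]] + S[tr[1], tr[3]],
              S[tr[2], tr[1]] + S[tr[2], tr[3]],
              S[tr[3], tr[1]] + S[tr[3], tr[2]])
      if (choiceModel == "deterministic") {
        cand <- which(sc == min(sc))
        if (length(cand) > 1) cand <- sample(cand, 1)
        tr[cand]
      } else {
        w <- exp(-(sc - min(sc)) / temperature)
        tr[sample.int(3, 1, prob = w)]
      }
    })
  })
  data.frame(object_a = ids[triples[, 1]], object_b = ids[triples[, 2]],
             object_c = ids[triples[, 3]], chosen = ids[chosen],
             stringsAsFactors = FALSE)
}

#' Generate paired binary outcomes with controlled concordance
#'
#' Simulates per-item correct/incorrect outcomes under two conditions with
#' marginal success probabilities \code{pA}, \code{pB} and a controlled joint
#' success probability p11 (the concordance parameter). Feasible p11 values
#' lie in the Frechet interval [max(0, pA + pB - 1), min(pA, pB)].
#'
#' @param nItems number of items.
#' @param pA,pB marginal success probabilities in [0, 1].
#' @param concordance \code{"independent"} (p11 = pA pB), \code{"maximal"}
#'   (p11 = min(pA, pB)), \code{"minimal"} (p11 = max(0, pA + pB - 1)), or a
#'   numeric p11.
#' @param seed RNG seed.
#' @return data.frame with binary columns \code{a}, \code{b} (a
#'   PairedOutcomeTable for \code{\link{mcnemarTest}}).
#' @export
generatePairedOutcomes <- function(nItems, pA, pB,
                                   concordance = "independent", seed = 1) {
  stopifnot(nItems >= 1, pA >= 0, pA <= 1, pB >= 0, pB <= 1)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  p11 <- if (is.character(concordance)) {
    switch(match.arg(concordance, c("independent", "maximal", "minimal")),
           independent = pA * pB, maximal = hi, minimal = lo)
  } else as.numeric(concordance)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12)
    stop(sprintf(
      "infeasible concordance: p11 = %.4f outside the feasible range [%.4f, %.4f] for pA = %.3f, pB = %.3f",
      p11, lo, hi, pA, pB))
  p11 <- min(max(p11, lo), hi)
  probs <- c(p11, pA - p11, pB - p11, 1 - pA - pB + p11)  # 11, 10, 01, 00
  cell <- with_seed(seed, sample.int(4, nItems, replace = TRUE, prob = probs))
  data.frame(a = as.integer(cell %in% c(1, 2)),
             b = as.integer(cell %in% c(1, 3)))
}
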