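# Shared fixtures, built in code.

# RDM with a planted lower triangle (values filled in the documented
# row-major order d21, d31, d32, d41, ...).
planted_rdm <- function(values, labels = NULL) {
  n <- (1 + sqrt(1 + 8 * length(values))) / 2
  stopifnot(n == round(n))
  m <- matrix(0, n, n)
  k <- 0
  for (i in 2:n) for (j in 1:(i - 1)) {
    k <- k + 1
    m[i, j] <- m[j, i] <- values[k]
  }
  rdm(m, labels = labels %||% letters[1:n])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random RDM from gaussian activation patterns.
random_rdm <- function(n, p = 15, seed = 1) {
  set.seed(seed)
  computeRDM(matrix(rnorm(n * p), n, p,
                    dimnames = list(sprintf("s%02d", 1:n), NULL)))
}

# Planted object similarity in [0, 1] from the generator's shared latents.
planted_similarity <- function(nObjects = 8, seed = 1, latentDim = 6) {
  cfg <- syntheticConfig(nObjects = nObjects,
                         nManmade = floor(nObjects / 2),
                         layers = c(l1 = 16), latentDim = latentDim,
                         seed = seed)
  S <- attr(generateActivations(cfg), "plantedSimilarity")
  S01 <- (S + 1) / 2
  diag(S01) <- 1
  S01
}

# Brute-force direct-count oracle for the triplet similarity estimator:
# per pair, loop over trials and count.
oracle_triplet_similarity <- function(trials, labels) {
  n <- length(labels)
  sim <- matrix(NA_real_, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    x <- labels[i]; y <- labels[j]
    has <- apply(trials[, 1:3], 1, function(r) x %in% r && y %in% r)
    if (!any(has)) next
    third_chosen <- vapply(which(has), function(t) {
      third <- setdiff(unlist(trials[t, 1:3]), c(x, y))
      trials$chosen[t] == third
    }, logical(1))
    sim[i, j] <- sim[j, i] <- mean(third_chosen)
  }
  diag(sim) <- 1
  sim
}

upper_vec <- function(m) m[upper.tri(m)]
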