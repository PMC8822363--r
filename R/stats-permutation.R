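#' One-sided permutation p-value (add-one convention)
#'
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + n_{perm})}: the percentile
#' of null values that reaches or exceeds the empirical value, with the
#' observed statistic counted into its own null (guaranteeing validity and a
#' strictly positive p).
#'
#' @param nullSample numeric vector of the statistic under the null.
#' @param observed observed statistic.
#' @return p-value in (0, 1].
#' @export
oneSidedP <- function(nullSample, observed) {
  if (!length(nullSample)) stop("empty null sample")
  (1 + sum(nullSample >= observed)) / (1 + length(nullSample))
}

# Lower-triangle index pairs (row-major, i > j) for an n x n matrix.
lt_index <- function(n) {
  i <- rep.int(seq_len(n), seq_len(n) - 1L)  # 2,3,3,4,4,4,...
  j <- unlist(lapply(seq_len(n)[-1], function(r) seq_len(r - 1L)),
              use.names = FALSE)
  cbind(i = i, j = j)
}

# Spearman rho between a pre-ranked vector and a raw vector.
rho_vs_ranked <- function(ranked_a, raw_b) {
  stats::cor(ranked_a, rank(raw_b))
}

#' Mantel permutation test for RDM correlation
#'
#' Tests the significance of the Spearman correlation between two RDMs by
#' randomly relabeling the objects of one RDM: a random permutation is
#' applied jointly to rows and columns of \code{b} (preserving its geometry),
#' the correlation with \code{a} is recomputed, and the one-sided p-value is
#' the add-one percentile of null correlations reaching the observed one.
#'
#' @param a,b \linkS4class{RDM}s over the same labels.
#' @param nPerm number of label permutations (default 1000).
#' @param seed RNG seed.
#' @return a \linkS4class{PermutationResult}.
#' @export
mantelTest <- function(a, b, nPerm = 1000, seed = 1) {
  stopifnot(is(a, "RDM"), is(b, "RDM"))
  n <- length(a@labels)
  if (n < 4) stop("need at least 4 objects (too few distinct permutations)")
  b <- alignRDM(b, a@labels)
  observed <- rdmSpearman(a, b)
  idx <- lt_index(n)
  ra <- rank(a@values[idx])
  B <- b@values
  null <- with_seed(seed, vapply(seq_len(nPerm), function(k) {
    p <- sample.int(n)
    rho_vs_ranked(ra, B[cbind(p[idx[, 1]], p[idx[, 2]])])
  }, numeric(1)))
  new("PermutationResult", observed = observed, nullSample = null,
      p = oneSidedP(null, observed), nPerm = as.integer(nPerm),
      seed = check_seed(seed), statistic = "RDM Spearman rho (Mantel)")
}

#' Exhaustive Mantel test (small n)
#'
#' Enumerates all n! object relabelings; used as the exact reference for the
#' Monte-Carlo \code{\link{mantelTest}}.
#'
#' @param a,b \linkS4class{RDM}s with few objects (n <= 7).
#' @return a \linkS4class{PermutationResult} whose null sample holds all n!
#'   permuted correlations (the identity included).
#' @export
mantelTestExact <- function(a, b) {
  stopifnot(is(a, "RDM"), is(b, "RDM"))
  n <- length(a@labels)
  if (n > 7) stop("exhaustive enumeration limited to n <= 7")
  b <- alignRDM(b, a@labels)
  observed <- rdmSpearman(a, b)
  idx <- lt_index(n)
  ra <- rank(a@values[idx])
  B <- b@values
  perms <- all_permutations(n)
  null <- vapply(perms, function(p) {
    rho_vs_ranked(ra, B[cbind(p[idx[, 1]], p[idx[, 2]])])
  }, numeric(1))
  # exact p: proportion of the full permutation distribution >= observed
  p <- sum(null >= observed - 1e-12) / length(null)
  new("PermutationResult", observed = observed, nullSample = null,
      p = p, nPerm = length(null), seed = 0L,
      statistic = "RDM Spearman rho (exhaustive Mantel)")
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos - 1L)
  }
  out
}

#' Difference between two RDM correlations sharing a reference RDM
#'
#' Tests whether \code{rho(shared, x)} exceeds \code{rho(shared, y)}. The null
#' shuffles the object labels of the shared RDM (jointly for rows and
#' columns), recomputes both correlations, and takes their difference.
#'
#' @param shared,x,y label-aligned \linkS4class{RDM}s.
#' @param nPerm permutations (default 1000).
#' @param seed RNG seed.
#' @return a \linkS4class{PermutationResult}; \code{observed} is
#'   \code{rho(shared, x) - rho(shared, y)} and \code{p} is one-sided for a
#'   positive difference (swap \code{x} and \code{y} for the other
#'   direction, which exactly negates the observed statistic).
#' @export
rdmCorrelationDifferenceTest <- function(shared, x, y, nPerm = 1000,
                                         seed = 1) {
  rdmPairDifferenceTest(shared, x, shared, y, nPerm = nPerm, seed = seed)
}

#' Difference between two arbitrary RDM correlations
#'
#' Generalization of \code{\link{rdmCorrelationDifferenceTest}} to two
#' correlations with no shared RDM (e.g. the same depiction pair in two
#' different networks): the observed statistic is
#' \code{rho(a1, b1) - rho(a2, b2)}, and the null applies one random object
#' relabeling jointly to \code{a1} and \code{a2} before recomputing both
#' correlations. When \code{a1} and \code{a2} are the same RDM this is the
#' shared-reference test.
#'
#' @param a1,b1 RDM pair of the first correlation.
#' @param a2,b2 RDM pair of the second correlation (same label set).
#' @param nPerm permutations.
#' @param seed RNG seed.
#' @return a \linkS4class{PermutationResult}.
#' @export
rdmPairDifferenceTest <- function(a1, b1, a2, b2, nPerm = 1000, seed = 1) {
  stopifnot(is(a1, "RDM"), is(b1, "RDM"), is(a2, "RDM"), is(b2, "RDM"))
  labels <- a1@labels
  b1 <- alignRDM(b1, labels); a2 <- alignRDM(a2, labels)
  b2 <- alignRDM(b2, labels)
  n <- length(labels)
  idx <- lt_index(n)
  rb1 <- rank(b1@values[idx])
  rb2 <- rank(b2@values[idx])
  A1 <- a1@values; A2 <- a2@values
  observed <- rho_vs_ranked(rb1, A1[idx]) - rho_vs_ranked(rb2, A2[idx])
  null <- with_seed(seed, vapply(seq_len(nPerm), function(k) {
    p <- sample.int(n)
    pi <- cbind(p[idx[, 1]], p[idx[, 2]])
    rho_vs_ranked(rb1, A1[pi]) - rho_vs_ranked(rb2, A2[pi])
  }, numeric(1)))
  new("PermutationResult", observed = observed, nullSample = null,
      p = oneSidedP(null, observed), nPerm = as.integer(nPerm),
      seed = check_seed(seed),
      statistic = "difference of RDM Spearman correlations")
}

#' Across-layer variation test for an RDM-correlation profile
#'
#' Tests whether the cross-depiction RDM correlation varies across layers.
#' The statistic is the sum of squared deviations of the per-layer
#' correlations from their across-layer mean. The null draws one object
#' relabeling per depiction — the same shuffling across layers, a different
#' (independent) shuffling for the two depictions — and recomputes the
#' statistic.
#'
#' @param rdmsX,rdmsY lists of \linkS4class{RDM}s, one per layer, for the two
#'   depictions entering the correlation (same layer order).
#' @param nPerm permutations (default 1000).
#' @param seed RNG seed.
#' @return a \linkS4class{PermutationResult}.
#' @export
acrossLayerVariationTest <- function(rdmsX, rdmsY, nPerm = 1000, seed = 1) {
  if (length(rdmsX) < 2 || length(rdmsX) != length(rdmsY))
    stop("need RDM pairs for at least 2 layers")
  labels <- rdmsX[[1]]@labels
  rdmsX <- lapply(rdmsX, alignRDM, labels = labels)
  rdmsY <- lapply(rdmsY, alignRDM, labels = labels)
  n <- length(labels)
  idx <- lt_index(n)
  Xv <- lapply(rdmsX, function(r) r@values)
  Yv <- lapply(rdmsY, function(r) r@values)
  stat_for <- function(px, py) {
    pxi <- cbind(px[idx[, 1]], px[idx[, 2]])
    pyi <- cbind(py[idx[, 1]], py[idx[, 2]])
    rhos <- mapply(function(X, Y) {
      stats::cor(rank(X[pxi]), rank(Y[pyi]))
    }, Xv, Yv)
    sum((rhos - mean(rhos))^2)
  }
  id <- seq_len(n)
  observed <- stat_for(id, id)
  null <- with_seed(seed, vapply(seq_len(nPerm), function(k) {
    stat_for(sample.int(n), sample.int(n))
  }, numeric(1)))
  new("PermutationResult", observed = observed, nullSample = null,
      p = oneSidedP(null, observed), nPerm = as.integer(nPerm),
      seed = check_seed(seed),
      statistic = "sum of squared deviations of layerwise rho from mean")
}

#' Sign-permutation test of human vs. network accuracy
#'
#' The observed statistic is mean(per-object human accuracies) minus the
#' network accuracy. The null flips the sign of each object's accuracy
#' independently with probability 1/2, subtracts the network accuracy from
#' the mean of the flipped values, and repeats. The signs of the accuracy
#' values themselves are flipped (see \code{flipDifferences} for the variant
#' that flips the per-object human-minus-network differences instead).
#'
#' @param humanAcc per-object accuracies in [0, 1].
#' @param cnnAcc scalar network accuracy.
#' @param nPerm permutations (default 1000).
#' @param seed RNG seed.
#' @param flipDifferences if TRUE, flip signs of \code{humanAcc - cnnAcc}
#'   per object instead of the raw accuracies.
#' @return a \linkS4class{PermutationResult}.
#' @export
signPermutationTest <- function(humanAcc, cnnAcc, nPerm = 1000, seed = 1,
                                flipDifferences = FALSE) {
  if (!length(humanAcc)) stop("empty accuracy vector")
  stopifnot(all(humanAcc >= 0 & humanAcc <= 1), length(cnnAcc) == 1)
  observed <- mean(humanAcc) - cnnAcc
  m <- length(humanAcc)
  vals <- if (flipDifferences) humanAcc - cnnAcc else humanAcc
  null <- with_seed(seed, vapply(seq_len(nPerm), function(k) {
    s <- sample(c(-1, 1), m, replace = TRUE)
    if (flipDifferences) mean(s * vals) else mean(s * vals) - cnnAcc
  }, numeric(1)))
  new("PermutationResult", observed = observed, nullSample = null,
      p = oneSidedP(null, observed), nPerm = as.integer(nPerm),
      seed = check_seed(seed),
      statistic = "mean(human accuracy) - network accuracy")
}

#' Permutation null for decoding accuracy
#'
#' Tests whether a cross-validated decoding accuracy exceeds chance by
#' repeating the classification analysis with randomly shuffled class labels.
#'
#' @param acts an \linkS4class{ActivationSet} or numeric matrix (stimuli in
#'   rows).
#' @param labels class labels (e.g. manmade/natural); defaults to the
#'   \code{superordinate} column for an \code{ActivationSet}.
#' @param config a \code{\link{decodeConfig}}.
#' @param nPerm label permutations (default 1000).
#' @param seed RNG seed (also reseeds the cross-validation of each run).
#' @return a \linkS4class{PermutationResult}; \code{observed} is the mean
#'   accuracy with true labels.
#' @export
decodingPermutationNull <- function(acts, labels = NULL,
                                    config = decodeConfig(), nPerm = 1000,
                                    seed = 1) {
  xy <- resolve_decode_input(acts, labels)
  cfg <- config
  cfg$seed <- derive_seed(seed, 0)
  observed <- cvDecode(xy$x, xy$labels, cfg)@meanAccuracy
  perms <- with_seed(derive_seed(seed, 1),
                     lapply(seq_len(nPerm),
                            function(k) sample(xy$labels)))
  null <- vapply(seq_len(nPerm), function(k) {
    cfg$seed <- derive_seed(seed, k + 1)
    cvDecode(xy$x, perms[[k]], cfg)@meanAccuracy
  }, numeric(1))
  new("PermutationResult", observed = observed, nullSample = null,
      p = oneSidedP(null, observed), nPerm = as.integer(nPerm),
      seed = check_seed(seed),
      statistic = "mean cross-validated decoding accuracy")
}

#' JSON record of a permutation test
#'
#' @param x a \linkS4class{PermutationResult}.
#' @param family optional FDR family tag.
#' @return a named list ready for \code{jsonlite::toJSON}.
#' @export
permutationRecord <- function(x, family = NA_character_) {
  stopifnot(is(x, "PermutationResult"))
  list(statistic = x@statistic, observed = x@observed, p = x@p,
       n_perm = x@nPerm, seed = x@seed, family = family)
}
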