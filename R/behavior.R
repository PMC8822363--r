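#' Estimate pairwise similarity from triplet odd-one-out choices
#'
#' For every unordered object pair (x, y), the similarity is the probability
#' of x and y being kept together: the ratio of trials containing both x and
#' y in which the third object z was chosen as the odd one out, over all
#' trials containing x and y. Co-occurrence counts per pair are recorded;
#' pairs that never co-occurred are flagged undefined (NA), never silently
#' zero.
#'
#' @param trials TripletDataset: data.frame with columns \code{object_a},
#'   \code{object_b}, \code{object_c}, \code{chosen}.
#' @param labels object identifiers fixing the matrix order; defaults to the
#'   sorted ids appearing in the trials.
#' @return a \linkS4class{PairwiseChoiceSimilarity}.
#' @export
tripletSimilarity <- function(trials, labels = NULL) {
  need <- c("object_a", "object_b", "object_c", "chosen")
  stopifnot(all(need %in% colnames(trials)))
  if (!nrow(trials)) stop("empty trial table")
  tri <- cbind(as.character(trials$object_a), as.character(trials$object_b),
               as.character(trials$object_c))
  chosen <- as.character(trials$chosen)
  if (is.null(labels)) labels <- sort(unique(as.vector(tri)))
  n <- length(labels)
  bad <- which(chosen != tri[, 1] & chosen != tri[, 2] & chosen != tri[, 3])
  if (length(bad))
    stop("chosen id not among the triplet's objects in trial(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(tri[, 1] == tri[, 2] | tri[, 1] == tri[, 3] | tri[, 2] == tri[, 3]))
    stop("triplet object ids must be distinct within a trial")
  ia <- match(tri[, 1], labels); ib <- match(tri[, 2], labels)
  ic <- match(tri[, 3], labels)
  if (anyNA(c(ia, ib, ic))) stop("trial contains ids absent from labels")
  ichosen <- match(chosen, labels)
  counts <- matrix(0L, n, n)
  together <- matrix(0L, n, n)
  add_pair <- function(m, i, j) {
    idx <- cbind(pmin(i, j), pmax(i, j))
    tab <- table(idx[, 1] + (idx[, 2] - 1) * n)
    pos <- as.integer(names(tab))
    m[pos] <- m[pos] + as.integer(tab)
    m
  }
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    i <- cbind(ia, ib, ic)[, pair[1]]
    j <- cbind(ia, ib, ic)[, pair[2]]
    counts <- add_pair(counts, i, j)
    # the pair is "kept together" when the remaining object was chosen
    other <- ia + ib + ic - i - j
    sel <- ichosen == other
    if (any(sel)) together <- add_pair(together, i[sel], j[sel])
  }
  sim <- ifelse(counts > 0, together / pmax(counts, 1L), NA_real_)
  sim[lower.tri(sim)] <- t(sim)[lower.tri(sim)]
  counts[lower.tri(counts)] <- t(counts)[lower.tri(counts)]
  diag(sim) <- 1
  diag(counts) <- 0L
  new("PairwiseChoiceSimilarity", labels = labels, sim = sim,
      counts = counts)
}

#' Convert choice similarities to an RDM
#'
#' Behavioral dissimilarity is defined as \eqn{d(x, y) = 1 - sim(x, y)} with
#' a zero diagonal, making triplet-derived similarity comparable to network
#' RDMs via \code{\link{rdmSpearman}}.
#'
#' @param x a \linkS4class{PairwiseChoiceSimilarity} with all pairs defined.
#' @return an \linkS4class{RDM}.
#' @export
choiceSimilarityToRDM <- function(x) {
  stopifnot(is(x, "PairwiseChoiceSimilarity"))
  undef <- which(is.na(x@sim) & upper.tri(x@sim), arr.ind = TRUE)
  if (nrow(undef))
    stop("undefined pairs (never co-occurred): ",
         paste(sprintf("(%s, %s)", x@labels[undef[, 1]],
                       x@labels[undef[, 2]]), collapse = ", "))
  d <- 1 - x@sim
  diag(d) <- 0
  rdm(d, labels = x@labels)
}

#' Score labeling responses against a synonym answer key
#'
#' A response is correct if, after case-folding and whitespace trimming, it
#' matches the object's category label exactly or any entry of its synonym
#' set. The synonym key is data (a table or TSV), not a built-in lexicon.
#'
#' @param responses data.frame with columns \code{object_id},
#'   \code{response} (one row per respondent x object).
#' @param answerKey data.frame with columns \code{object_id},
#'   \code{synonym} (one row per accepted label; include the canonical label
#'   itself), or the path of such a TSV.
#' @return list with \code{perObject} (named vector of per-object accuracy)
#'   and \code{mean} (mean accuracy over objects).
#' @export
labelAccuracy <- function(responses, answerKey) {
  if (is.character(answerKey))
    answerKey <- utils::read.delim(answerKey, stringsAsFactors = FALSE)
  stopifnot(all(c("object_id", "response") %in% colnames(responses)),
            all(c("object_id", "synonym") %in% colnames(answerKey)))
  norm <- function(x) tolower(trimws(as.character(x)))
  missing_obj <- setdiff(unique(responses$object_id),
                         unique(answerKey$object_id))
  if (length(missing_obj))
    stop("object(s) missing from answer key: ",
         paste(missing_obj, collapse = ", "))
  key <- split(norm(answerKey$synonym), answerKey$object_id)
  correct <- mapply(function(obj, resp) norm(resp) %in% key[[obj]],
                    responses$object_id, responses$response,
                    USE.NAMES = FALSE)
  per <- vapply(split(correct, responses$object_id), mean, numeric(1))
  list(perObject = per, mean = mean(per))
}
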