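#' McNemar test of homogeneity on paired binary outcomes
#'
#' Compares two paired proportions (e.g. per-item correct/incorrect under two
#' conditions) through the discordant counts b (A correct, B incorrect) and
#' c (A incorrect, B correct): \eqn{\chi^2 = (b - c)^2 / (b + c)} with 1
#' degree of freedom, by default without continuity correction.
#'
#' @param outcomes a two-column 0/1 matrix or data.frame (condition A,
#'   condition B), one row per item.
#' @param correct apply the Edwards continuity correction
#'   \eqn{(|b-c|-1)^2/(b+c)} (default FALSE).
#' @return list with \code{chi2}, \code{p}, \code{b}, \code{c}.
#' @export
mcnemarTest <- function(outcomes, correct = FALSE) {
  m <- as.matrix(outcomes)
  if (ncol(m) != 2) stop("outcomes must have two columns (conditions A, B)")
  if (!all(m %in% c(0, 1))) stop("outcomes must be binary 0/1")
  b <- sum(m[, 1] == 1 & m[, 2] == 0)
  cc <- sum(m[, 1] == 0 & m[, 2] == 1)
  if (b + cc == 0)
    stop("no discordant pairs: the McNemar test is undefined (b + c = 0)")
  chi2 <- if (correct) (abs(b - cc) - 1)^2 / (b + cc) else
    (b - cc)^2 / (b + cc)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       b = b, c = cc)
}

#' Two one-sided tests (TOST) for equivalence of paired means
#'
#' Declares the mean paired difference equivalent to zero within
#' \code{bounds} when both one-sided paired t-tests reject: difference >
#' lower bound and difference < upper bound. The reported p is the maximum of
#' the two one-sided p-values; equivalence holds at level alpha when p <
#' alpha.
#'
#' @param x,y paired samples of equal length.
#' @param bounds numeric length-2 equivalence bounds (low < high), on the
#'   scale of \code{x - y}. The bounds are a required analysis input; no
#'   default is supplied.
#' @param alpha significance level for the reported decision (default 0.05).
#' @return list with \code{p}, \code{decision} (logical), \code{t_lower},
#'   \code{t_upper}, \code{df}, \code{mean_diff}.
#' @details With zero variance of the differences the t statistics are
#'   degenerate; the limit is reported: p = 0 if the mean difference lies
#'   strictly inside the bounds, else p = 1.
#' @export
tostEquivalence <- function(x, y, bounds, alpha = 0.05) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  if (length(bounds) != 2 || bounds[1] >= bounds[2])
    stop("bounds must be (low, high) with low < high")
  d <- x - y
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  md <- mean(d)
  sdd <- stats::sd(d)
  df <- n - 1
  if (sdd == 0) {
    inside <- md > bounds[1] && md < bounds[2]
    p <- if (inside) 0 else 1
    return(list(p = p, decision = p < alpha, t_lower = Inf * sign(md - bounds[1]),
                t_upper = -Inf * sign(md - bounds[2]), df = df,
                mean_diff = md))
  }
  se <- sdd / sqrt(n)
  t_lower <- (md - bounds[1]) / se   # H1: diff > low
  t_upper <- (md - bounds[2]) / se   # H1: diff < high
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  p <- max(p_lower, p_upper)
  list(p = p, decision = p < alpha, t_lower = t_lower, t_upper = t_upper,
       df = df, mean_diff = md)
}

#' Two-sided independent t-test with pooled variance
#'
#' Classic two-sample t statistic with pooled variance and
#' \eqn{df = n_x + n_y - 2}; delegates to \code{stats::t.test(var.equal =
#' TRUE)}.
#'
#' @param x,y independent samples (each n >= 2).
#' @return list with \code{t}, \code{p}, \code{df}.
#' @export
independentTTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1,
                                        df = length(x) + length(y) - 2))
    stop("zero pooled variance with unequal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' clipped at 1 and returned in input order (via
#' \code{stats::p.adjust(method = "BH")}).
#'
#' @param pvals vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bhFDR <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Apply BH-FDR within configured test families
#'
#' @param results data.frame with at least columns \code{p} and
#'   \code{family}; adjustment is applied separately within each family.
#' @return the data.frame with an added \code{p_adj} column.
#' @export
fdrWithinFamilies <- function(results) {
  stopifnot(all(c("p", "family") %in% colnames(results)))
  results$p_adj <- NA_real_
  for (f in unique(results$family)) {
    sel <- results$family == f
    results$p_adj[sel] <- bhFDR(results$p[sel])
  }
  results
}
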