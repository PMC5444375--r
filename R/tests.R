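#' @include utils.R
NULL

#' Number of level-count compositions the exact test enumerates
#'
#' The exact multinomial test enumerates every vector of non-negative
#' integer counts over \code{m} levels summing to \code{n}; there are
#' \code{choose(n + m - 1, m - 1)} of them.  A pathway of 30 genes over 3
#' levels gives 496 outcomes; 100 genes give 5,151.
#'
#' @param n total number of genes in the pathway.
#' @param m number of variability levels.
#' @return the number of outcome vectors.
#' @export
countCompositions <- function(n, m) {
  choose(n + m - 1, m - 1)
}

# All compositions of n into m non-negative parts, one row each.
.compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, 1L, 1L))
  do.call(rbind, lapply(0:n, function(k) {
    cbind(k, .compositions(n - k, m - 1L))
  }))
}

# Drop levels impossible under the null (p_i = 0).  A positive count on a
# zero-probability level is an error; a zero count on one contributes
# nothing, so removing the level is equivalent to merging it into a
# neighbour.
.dropZeroLevels <- function(counts, probs) {
  zero <- probs == 0
  if (any(zero & counts > 0))
    .dsStop("observed count > 0 on a level with null probability 0",
            "disperset_input_error")
  if (any(zero)) {
    counts <- counts[!zero]
    probs <- probs[!zero] / sum(probs[!zero])
  }
  list(counts = counts, probs = probs)
}

# Full enumeration of the multinomial outcome space for a given (n, p):
# log-probabilities sorted ascending with their cumulative probability, so
# a p-value is a single indexed lookup.  Reused by the Monte-Carlo and
# power code paths.
.exactEnum <- function(n, probs) {
  m <- length(probs)
  comp <- .compositions(n, m)
  lp <- lgamma(n + 1) - rowSums(lgamma(comp + 1)) +
    as.vector(comp %*% log(probs))
  ord <- order(lp)
  lpSorted <- lp[ord]
  cum <- cumsum(exp(lpSorted))
  list(n = n, probs = probs, logp = lpSorted, cum = cum,
       outcomes = nrow(comp))
}

.logProbMultinom <- function(counts, probs) {
  n <- sum(counts)
  lgamma(n + 1) - sum(lgamma(counts + 1)) + sum(counts * log(probs))
}

# p-value from a precomputed enumeration, including ties up to a relative
# tolerance so the observed outcome always contributes (guarantees p > 0).
.exactPFromEnum <- function(enum, lpObs, tieTol = 1e-9) {
  idx <- findInterval(lpObs + log1p(tieTol), enum$logp)
  min(1, enum$cum[max(idx, 1L)])
}

#' Exact multinomial goodness-of-fit test
#'
#' Tests observed level counts against a null probability vector by full
#' enumeration: the p-value is the total probability of every outcome
#' vector whose multinomial probability does not exceed the observed
#' outcome's (ties included up to a relative tolerance of \code{1e-9}, so
#' the observed outcome always contributes and the p-value is strictly
#' positive).  Log-probabilities are used throughout for numerical
#' stability.
#'
#' The outcome space has \code{choose(n + m - 1, m - 1)} vectors; above
#' \code{cap} the test refuses to enumerate and asks for the chi-squared
#' approximation (\code{\link{chisqGofTest}}) or the Monte-Carlo fallback
#' (\code{\link{monteCarloMultinomialTest}}) instead.
#'
#' @param counts observed non-negative integer counts per level.
#' @param probs null probabilities per level (summing to 1); levels with
#'   probability 0 and count 0 are removed before testing, a positive count
#'   on such a level is an error.
#' @param cap maximum number of outcome vectors to enumerate (default
#'   2e6).
#' @return the p-value, with attributes \code{outcomes} (number of outcome
#'   vectors enumerated) and \code{method = "exact"}.
#' @examples
#' exactMultinomialTest(c(2, 0), c(0.5, 0.5))  # 0.5
#' @export
exactMultinomialTest <- function(counts, probs, cap = 2e6) {
  counts <- .checkCounts(counts)
  probs <- .checkProbVector(probs)
  if (length(counts) != length(probs))
    .dsStop("counts and probs must have the same length")
  cl <- .dropZeroLevels(counts, probs)
  counts <- cl$counts; probs <- cl$probs
  n <- sum(counts)
  if (n < 1L) .dsStop("total count must be >= 1")
  ncomp <- countCompositions(n, length(counts))
  if (ncomp > cap)
    .dsStop(sprintf(paste0("enumeration size %.0f exceeds the cap (%.0f); ",
                           "use chisqGofTest() or monteCarloMultinomialTest()"),
                    ncomp, cap),
            "disperset_cap_error")
  enum <- .exactEnum(n, probs)
  p <- .exactPFromEnum(enum, .logProbMultinom(counts, probs))
  structure(p, outcomes = enum$outcomes, method = "exact")
}

#' Monte-Carlo multinomial goodness-of-fit test
#'
#' Seeded fallback for count vectors whose outcome space is too large to
#' enumerate: draws \code{reps} multinomial outcomes under the null and
#' estimates the p-value as \code{(1 + #\{draws no more probable than the
#' observed outcome\}) / (reps + 1)}.
#'
#' @inheritParams exactMultinomialTest
#' @param reps number of simulated outcomes (at least 1000).
#' @param seed integer seed for reproducibility.
#' @return p-value with attributes \code{reps} and
#'   \code{method = "montecarlo"}.
#' @export
monteCarloMultinomialTest <- function(counts, probs, reps = 10000L,
                                      seed = NULL) {
  counts <- .checkCounts(counts)
  probs <- .checkProbVector(probs)
  if (length(counts) != length(probs))
    .dsStop("counts and probs must have the same length")
  if (reps < 1000L) .dsStop("reps must be >= 1000")
  cl <- .dropZeroLevels(counts, probs)
  counts <- cl$counts; probs <- cl$probs
  n <- sum(counts)
  if (n < 1L) .dsStop("total count must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(reps, n, probs)
  lp <- lgamma(n + 1) - colSums(lgamma(draws + 1)) +
    as.vector(log(probs) %*% draws)
  lpObs <- .logProbMultinom(counts, probs)
  p <- (1 + sum(lp <= lpObs + log1p(1e-9))) / (reps + 1)
  structure(p, reps = as.integer(reps), method = "montecarlo")
}

#' Chi-squared goodness-of-fit test
#'
#' Asymptotic alternative to the exact test: \eqn{X^2 = \sum_i (O_i -
#' E_i)^2 / E_i} with expected counts \eqn{E_i = n p_i}, referred to the
#' upper tail of the chi-squared distribution with \eqn{m - 1} degrees of
#' freedom.  The approximation improves as the pathway size \eqn{n} grows.
#'
#' @inheritParams exactMultinomialTest
#' @return list with elements \code{statistic}, \code{df} and
#'   \code{p.value}.
#' @export
chisqGofTest <- function(counts, probs) {
  counts <- .checkCounts(counts)
  probs <- .checkProbVector(probs)
  if (length(counts) != length(probs))
    .dsStop("counts and probs must have the same length")
  cl <- .dropZeroLevels(counts, probs)
  counts <- cl$counts; probs <- cl$probs
  n <- sum(counts)
  if (n < 1L) .dsStop("total count must be >= 1")
  e <- n * probs
  x2 <- sum((counts - e)^2 / e)
  df <- length(counts) - 1L
  p <- if (df == 0L) 1 else stats::pchisq(x2, df, lower.tail = FALSE)
  list(statistic = x2, df = df, p.value = p)
}

#' Two-group homogeneity test on level counts
#'
#' Tests whether the per-level count vectors of two groups were drawn from
#' the same underlying level distribution.  The default is the chi-squared
#' test of homogeneity on the 2 x m table with expected counts from the
#' pooled proportions (\code{m' - 1} degrees of freedom after dropping
#' levels empty in both groups).  The exact method tests the group-1 counts
#' against the group-2 proportions with \code{\link{exactMultinomialTest}};
#' when any group-2 level count is 0, 0.5 is added to every group-2 level
#' before normalizing so the null probabilities stay positive.
#'
#' @param counts1,counts2 integer count vectors over the same levels.
#' @param method \code{"chisq"} (default) or \code{"exact"}.
#' @param cap enumeration cap passed to the exact method.
#' @return list with \code{p.value}, \code{method}, and for the chi-squared
#'   method \code{statistic} and \code{df}.
#' @export
twoGroupTest <- function(counts1, counts2, method = c("chisq", "exact"),
                         cap = 2e6) {
  method <- match.arg(method)
  counts1 <- .checkCounts(counts1, "counts1")
  counts2 <- .checkCounts(counts2, "counts2")
  if (length(counts1) != length(counts2))
    .dsStop("count vectors must cover the same levels")
  if (sum(counts1) < 1L || sum(counts2) < 1L)
    .dsStop("each group must have at least one counted gene",
            "disperset_input_error")
  both0 <- counts1 == 0L & counts2 == 0L
  counts1 <- counts1[!both0]; counts2 <- counts2[!both0]
  if (method == "chisq") {
    tab <- rbind(counts1, counts2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    x2 <- sum((tab - e)^2 / e)
    df <- ncol(tab) - 1L
    p <- if (df == 0L) 1 else stats::pchisq(x2, df, lower.tail = FALSE)
    list(statistic = x2, df = df, p.value = p, method = "chisq")
  } else {
    q2 <- as.numeric(counts2)
    if (any(q2 == 0)) q2 <- q2 + 0.5
    p <- exactMultinomialTest(counts1, q2 / sum(q2), cap = cap)
    list(p.value = as.numeric(p), method = "exact",
         outcomes = attr(p, "outcomes"))
  }
}

#' Per-level binomial deviation test
#'
#' Localizes a pathway signal to individual variability levels: the count
#' in one level is tested against its null proportion with a two-sided
#' exact binomial test using the doubling rule, \code{min(1, 2 *
#' min(P(X <= O), P(X >= O)))}.  The direction is \code{"up"} when the
#' observed count is at or above its expectation \code{n * p}, else
#' \code{"down"}.
#'
#' @param observed count of pathway genes in the level.
#' @param n total pathway genes.
#' @param p null proportion for the level, strictly inside (0, 1).
#' @return list with \code{p.value} and \code{direction}.
#' @export
binomialLevelTest <- function(observed, n, p) {
  if (length(observed) != 1L || length(n) != 1L || length(p) != 1L)
    .dsStop("binomialLevelTest is scalar")
  observed <- .checkCounts(observed, "observed")
  n <- .checkCounts(n, "n")
  if (observed > n) .dsStop("observed must be <= n")
  if (!is.numeric(p) || is.na(p) || p <= 0 || p >= 1)
    .dsStop("p must lie strictly between 0 and 1", "disperset_input_error")
  pl <- stats::pbinom(observed, n, p)
  pu <- stats::pbinom(observed - 1L, n, p, lower.tail = FALSE)
  list(p.value = min(1, 2 * min(pl, pu)),
       direction = if (observed >= n * p) "up" else "down")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment across all tested pathways of
#' one collection (delegates to \code{stats::p.adjust} after validating the
#' input range).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    .dsStop("p-values must lie in [0, 1] with no NAs", "disperset_input_error")
  stats::p.adjust(p, method = "BH")
}
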