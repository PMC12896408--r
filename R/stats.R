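# Self-contained cores for the cohort statistics: Spearman rank correlation
# with an exact permutation p-value at small n, Fisher's exact test by full
# enumeration of the hypergeometric support, and Pearson's chi-square.
# Results are declared significant at p <= 0.05 in reports.

# all permutations of 1..n as an (n! x n) matrix, built by insertion
permutationsMatrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- permutationsMatrix(n - 1L)
  m <- nrow(p)
  out <- matrix(0L, m * n, n)
  for (pos in seq_len(n)) {
    rows <- ((pos - 1L) * m + 1L):(pos * m)
    if (pos > 1L) out[rows, seq_len(pos - 1L)] <- p[, seq_len(pos - 1L)]
    out[rows, pos] <- n
    if (pos < n) out[rows, (pos + 1L):n] <- p[, pos:(n - 1L)]
  }
  out
}

# midranks (average ranks for ties)
midrank <- function(x) rank(x, ties.method = "average")

# Pearson correlation of two rank vectors, written out
rankCorrelation <- function(rx, ry) {
  n <- length(rx)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

#' Spearman rank correlation
#'
#' Correlation of midranks.  The two-sided p-value is exact for `n <= 9` —
#' enumeration of all `n!` permutations of one rank vector, counting those
#' whose absolute correlation reaches the observed one — and a
#' t-approximation with `n - 2` degrees of freedom otherwise.  A constant
#' input leaves rho undefined (`NA`, flagged in `method`).
#'
#' @param x,y numeric vectors of equal length (>= 3)
#' @param exactMaxN largest n at which the exact permutation null is used
#' @return list `rho`, `p`, `method` (`"exact_permutation"`,
#'   `"t_approximation"` or `"undefined"`), `n`, `significant`
#' @export
spearmanTest <- function(x, y, exactMaxN = 9) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3) stop("need at least 3 complete observations")
  rx <- midrank(x); ry <- midrank(y)
  rho <- rankCorrelation(rx, ry)
  if (is.na(rho))
    return(list(rho = NA_real_, p = NA_real_, method = "undefined", n = n,
                significant = NA))
  if (n <= exactMaxN) {
    perms <- permutationsMatrix(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    den <- sqrt(sum(rxc^2) * sum(ryc^2))
    num <- matrix(ryc[perms], nrow(perms), n) %*% rxc
    rhos <- as.numeric(num) / den
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(p, 1)
    method <- "t_approximation"
  }
  list(rho = rho, p = p, method = method, n = n, significant = p <= 0.05)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by full enumeration of the hypergeometric support with
#' both margins fixed: the sum of the probabilities of every table at most
#' as probable as the observed one (with 1e-7 relative tolerance on the
#' comparison).
#'
#' @param tab 2x2 matrix of non-negative counts
#' @return list `p`, `oddsTable`, `significant`
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (sum(tab) == 0) stop("all-zero table")
  m <- sum(tab[1, ])          # row-1 margin
  nn <- sum(tab[2, ])         # row-2 margin
  k <- sum(tab[, 1])          # column-1 margin
  support <- max(0, k - nn):min(k, m)
  probs <- stats::dhyper(support, m, nn, k)
  pObs <- stats::dhyper(tab[1, 1], m, nn, k)
  p <- sum(probs[probs <= pObs * (1 + 1e-7)])
  p <- min(p, 1)
  list(p = p, oddsTable = tab, significant = p <= 0.05)
}

#' Pearson chi-square test of independence
#'
#' Statistic `sum((O - E)^2 / E)` on an r x c table with
#' `df = (r - 1)(c - 1)` and an upper-tail chi-square p-value; no
#' continuity correction.  A zero expected count is an explicit error
#' (Fisher's exact test is the appropriate fallback).
#'
#' @param tab r x c matrix of counts
#' @return list `statistic`, `df`, `p`, `expected`, `significant`
#' @export
chiSquareTest <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0))
    stop("zero expected count; use fisherExact2x2() instead")
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, expected = expected,
       significant = p <= 0.05)
}
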