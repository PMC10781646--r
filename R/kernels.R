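# Shared statistical kernels: rank-sum test, hypergeometric tail, pair AUC.
# Every differential-expression, programme-significance and enrichment test
# in the package goes through rankSumTest() so the exact-vs-approximate
# behaviour is uniform.

# exact two-sided p by dynamic programming over the distribution of the
# rank sum of n1 items drawn from the observed (mid)ranks; ties are handled
# naturally because the DP runs on the observed rank multiset.  Midranks are
# doubled so all sums are integers.
.exactRankSumP <- function(r, n1, w) {
  r2 <- as.integer(round(2 * r))
  S <- sum(r2)
  # f[j + 1, s + 1] = number of size-j subsets with doubled rank sum s
  f <- matrix(0, nrow = n1 + 1, ncol = S + 1)
  f[1L, 1L] <- 1
  for (v in r2) {
    jmax <- n1
    for (j in seq.int(jmax, 1L)) {
      src <- f[j, seq_len(S + 1L - v)]
      if (any(src != 0))
        f[j + 1L, (v + 1L):(S + 1L)] <- f[j + 1L, (v + 1L):(S + 1L)] + src
    }
  }
  dist <- f[n1 + 1L, ]
  tot <- sum(dist)
  w2 <- as.integer(round(2 * w))
  pLower <- sum(dist[seq_len(w2 + 1L)]) / tot
  pUpper <- sum(dist[(w2 + 1L):(S + 1L)]) / tot
  min(1, 2 * min(pLower, pUpper))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact tie-aware p-values by full enumeration of the rank-sum distribution
#' when both groups have at most eight observations (the two-sided p is twice
#' the smaller tail, capped at 1); otherwise a tie-corrected normal
#' approximation without continuity correction.
#'
#' @param x,y numeric vectors for the two groups (each non-empty).
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) the exact path;
#'   default \code{NULL} uses it when both groups have <= 8 values.
#' @return list with \code{statistic} (Mann-Whitney U for \code{x}) and
#'   \code{p}.
#' @examples
#' rankSumTest(c(1, 2), c(3, 4))$p  # 1/3 by enumeration
#' @export
rankSumTest <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L)
    stop("both groups must be non-empty (got ", n1, " and ", n2, ")")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- n1 <= 8L && n2 <= 8L
  if (exact) {
    p <- .exactRankSumP(r, n1, w)
  } else {
    N <- n1 + n2
    tie <- tabulate(match(r, unique(r)))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    p <- if (sigma2 <= 0) 1 else
      min(1, 2 * pnorm(-abs(u - n1 * n2 / 2) / sqrt(sigma2)))
  }
  list(statistic = u, p = p)
}

# vectorized large-sample rank-sum across matrix rows (genes); returns p and
# U per row.  idx1/idx2 are column indices of the two groups.
.rankSumRows <- function(mat, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); N <- n1 + n2
  sub <- mat[, c(idx1, idx2), drop = FALSE]
  ps <- numeric(nrow(sub)); us <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    v <- sub[i, ]
    r <- rank(v)
    w <- sum(r[seq_len(n1)])
    u <- w - n1 * (n1 + 1) / 2
    if (n1 <= 8L && n2 <= 8L) {
      p <- .exactRankSumP(r, n1, w)
    } else {
      tie <- tabulate(match(r, unique(r)))
      sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
      p <- if (sigma2 <= 0) 1 else
        min(1, 2 * pnorm(-abs(u - n1 * n2 / 2) / sqrt(sigma2)))
    }
    ps[i] <- p; us[i] <- u
  }
  list(p = ps, u = us)
}

#' Upper-tail hypergeometric test
#'
#' Probability of observing \code{k} or more successes when drawing \code{n}
#' items without replacement from a population of \code{N} containing
#' \code{K} successes.
#'
#' @param k observed successes in the draw.
#' @param N population size.
#' @param K successes in the population.
#' @param n draw size.
#' @return upper-tail p-value \eqn{P(X \ge k)}.
#' @export
hypergeometricTest <- function(k, N, K, n) {
  if (any(c(k, N, K, n) < 0) || K > N || n > N)
    stop("inconsistent hypergeometric parameters")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Rank-based AUC for two score vectors
#'
#' \eqn{P(X > Y) + P(X = Y)/2} computed from ranks (equivalent to pair
#' counting with ties scored one half).
#'
#' @param x scores for the positive class.
#' @param y scores for the negative class.
#' @return AUC in \[0, 1\].
#' @examples
#' pairAuc(c(2, 3), c(1, 2.5))  # 0.75
#' @export
pairAuc <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both score vectors must be non-empty")
  r <- rank(c(x, y))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
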