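# Exact rank statistics.
#
# Both tests return a two-sided p-value defined on the symmetric permutation
# distribution of the rank statistic: p = P(|W - E[W]| >= |w_obs - E[W]|).
# The exact distributions are computed by dynamic programming over the
# (tie-averaged) ranks, doubled so half-ranks become integers; this handles
# ties exactly, which stats::wilcox.test does not. Above the exact-size
# limits a normal approximation with continuity and tie correction is used.

# Distribution of the sum of a size-m subset of integer weights (counts of
# subsets achieving each sum). Returns a numeric vector indexed by sum+1.
subset_sum_counts <- function(weights, m) {
  total <- sum(weights)
  # dp[[j]] = counts over sums for subsets of size j-1
  dp <- matrix(0, nrow = m + 1, ncol = total + 1)
  dp[1, 1] <- 1
  for (w in weights) {
    jmax <- m
    for (j in seq(jmax, 1)) {
      src <- dp[j, ]
      if (any(src > 0)) {
        idx <- seq_len(total + 1 - w)
        dp[j + 1, idx + w] <- dp[j + 1, idx + w] + src[idx]
      }
    }
  }
  dp[m + 1, ]
}

# Distribution of the sum over all subsets (each weight in or out).
signflip_sum_counts <- function(weights) {
  total <- sum(weights)
  dp <- numeric(total + 1)
  dp[1] <- 1
  for (w in weights) {
    shifted <- c(rep(0, w), dp[seq_len(total + 1 - w)])
    dp <- dp + shifted
  }
  dp
}

#' Wilcoxon rank-sum test (exact with ties, two-sided)
#'
#' Exact permutation p-value on the rank-sum statistic for group sizes up to
#' `exact_max` per group; normal approximation with tie correction and
#' continuity correction beyond. Two-sided p is the probability of a
#' rank-sum deviating from its null mean at least as far as observed.
#'
#' @param x,y numeric samples.
#' @param exact_max exact computation is used when both groups have at most
#'   this many observations (default 50).
#' @return list with `statistic` (rank sum of `x`), `p.value`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 50) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stopf("both groups must be non-empty")
  n <- nx + ny
  r <- rank(c(x, y), ties.method = "average")
  w <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (nx <= exact_max && ny <= exact_max) {
    r2 <- as.integer(round(2 * r))
    counts <- subset_sum_counts(r2, nx)
    sums <- (seq_along(counts) - 1) / 2
    dev <- abs(sums - mu)
    obs <- abs(w - mu)
    p <- sum(counts[dev >= obs - 1e-9]) / choose(n, nx)
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    dev <- abs(w - mu)
    z <- max(0, dev - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
    method <- "normal approximation"
  }
  list(statistic = w, p.value = min(1, p), method = method)
}

#' Wilcoxon signed-rank test (exact with ties, two-sided, paired)
#'
#' Zero differences are dropped (if all differences are zero the p-value is
#' defined as 1). Exact sign-flip enumeration via dynamic programming for up
#' to `exact_max` non-zero differences; normal approximation with tie and
#' continuity correction beyond.
#'
#' @param d numeric vector of paired differences.
#' @param exact_max exact computation when at most this many non-zero
#'   differences (default 30).
#' @return list with `statistic` (positive-rank sum), `p.value`, `method`,
#'   `direction` ("up", "down" or "none": sign of the median difference).
#' @export
signed_rank_test <- function(d, exact_max = 30) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  direction <- if (m == 0) "none" else if (stats::median(d) > 0) "up"
               else if (stats::median(d) < 0) "down" else "none"
  if (m == 0) {
    return(list(statistic = 0, p.value = 1, method = "degenerate",
                direction = direction))
  }
  r <- rank(abs(d), ties.method = "average")
  w <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (m <= exact_max) {
    r2 <- as.integer(round(2 * r))
    counts <- signflip_sum_counts(r2)
    sums <- (seq_along(counts) - 1) / 2
    dev <- abs(sums - mu)
    obs <- abs(w - mu)
    p <- sum(counts[dev >= obs - 1e-9]) / 2^m
    method <- "exact"
  } else {
    sigma2 <- sum(r^2) / 4
    dev <- abs(w - mu)
    z <- max(0, dev - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-z)
    method <- "normal approximation"
  }
  list(statistic = w, p.value = min(1, p), method = method,
       direction = direction)
}
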