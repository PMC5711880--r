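# Nonparametric statistical primitives used throughout the pipeline. These
# are authored here (not delegated to stats::) because the exact variants
# matter: mid-ranks for ties, the rank-transform Welch construction, and the
# minimum-likelihood two-sided exact binomial p.

#' Hodges-Lehmann two-sample location estimate
#'
#' The median of all cross-sample pairwise differences `x_i - y_j`: a robust
#' estimate of the shift in location between two distributions, well suited
#' to small, skewed, unbalanced samples.
#'
#' @param x,y non-empty numeric samples.
#' @return The estimate, in the units of `x`.
#' @examples
#' hodges_lehmann(c(1, 2), c(3, 5))  # median of {-2, -4, -1, -3} = -2.5
#' @export
hodges_lehmann <- function(x, y) {
  if (!length(x) || !length(y)) stopf("samples must be non-empty")
  stats::median(as.vector(outer(x, y, `-`)))
}

#' Welch U-test (Welch's t-test on ranks)
#'
#' Pools the two samples, assigns mid-ranks (ties share averaged ranks) and
#' applies Welch's unequal-variance t-test to the two rank samples, with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. The
#' rank transform drops the normality assumption; the Welch form drops
#' homoscedasticity, giving a test of stochastic dominance that tolerates
#' unbalanced group sizes.
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return List with `statistic` (t on ranks), `df` (fractional), `p_value`
#'   and `method`. When all pooled values are identical the statistic is 0
#'   and p = 1.
#' @export
welch_u_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stopf("need at least 2 observations per sample")
  r <- rank(c(x, y))  # mid-ranks for ties
  r1 <- r[seq_len(n1)]
  r2 <- r[n1 + seq_len(n2)]
  v1 <- stats::var(r1); v2 <- stats::var(r2)
  if (v1 + v2 == 0) {
    return(list(statistic = 0, df = NA_real_, p_value = 1,
                method = "Welch t on ranks"))
  }
  se2 <- v1 / n1 + v2 / n2
  stat <- (mean(r1) - mean(r2)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(statistic = stat, df = df,
       p_value = 2 * stats::pt(-abs(stat), df),
       method = "Welch t on ranks")
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' The standard step-up procedure: adjusted `p_(i) = min_{j >= i} m p_(j)/j`
#' capped at 1, with rejections exactly where the adjusted p is at most `q`.
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param q FDR level in (0, 1).
#' @return List with `p_adjusted` (same order as input) and logical
#'   `reject`.
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  check_prob(q, "q")
  m <- length(p_values)
  o <- order(p_values)
  adj_sorted <- pmin(1, rev(cummin(rev(p_values[o] * m / seq_len(m)))))
  p_adjusted <- numeric(m)
  p_adjusted[o] <- adj_sorted
  list(p_adjusted = p_adjusted, reject = p_adjusted <= q)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks; two-sided p from
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#'
#' @param x,y paired numeric samples, n >= 3.
#' @return List with `rho`, `p_value`, `n`. Constant input gives `rho = NA`
#'   with a warning.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stopf("x and y must be paired")
  if (n < 3L) stopf("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Pearson correlation
#'
#' @param x,y paired numeric samples, n >= 2.
#' @return Pearson r, or `NA` with a warning for constant input.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired")
  if (length(x) < 2L) stopf("need at least 2 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warnf("constant input: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Exact two-sided binomial test
#'
#' Exact p-value by the minimum-likelihood rule: the sum of probabilities of
#' all outcomes no more likely than the observed count under
#' `Binomial(n, p0)`. Appropriate at the small per-fetus counts of this
#' design, where the normal approximation is unreliable.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, >= 1.
#' @param p0 null success probability.
#' @return The two-sided p-value.
#' @examples
#' binomial_test(10, 10)  # 2 / 1024
#' @export
binomial_test <- function(k, n, p0 = 0.5) {
  if (n < 1L || k < 0L || k > n) stopf("need 0 <= k <= n, n >= 1")
  check_prob(p0, "p0")
  d <- stats::dbinom(0:n, n, p0)
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided test of location between independent samples. Small problems
#' (up to `max_exact` subset enumerations) are solved by exact enumeration
#' of the rank-subset distribution, which handles ties transparently;
#' larger problems use the normal approximation with mid-rank tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples (n >= 1 each).
#' @param max_exact largest number of subsets to enumerate exactly.
#' @return List with `statistic` (Mann-Whitney U for `x`), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, max_exact = 40000) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stopf("samples must be non-empty")
  n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n, n1) <= max_exact) {
    subsets <- utils::combn(n, n1)
    u_all <- colSums(matrix(r[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u + eps), mean(u_all >= u - eps)))
    return(list(statistic = u, p_value = p, method = "exact enumeration"))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) {
    return(list(statistic = u, p_value = 1, method = "normal approximation"))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(statistic = u, p_value = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}
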