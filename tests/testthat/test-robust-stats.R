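test_that("hodges_lehmann matches all-pairs enumeration and its algebra", {
  expect_equal(hodges_lehmann(5, 2), 3)
  expect_equal(hodges_lehmann(c(1, 2), c(3, 5)), -2.5)

  # independent oracle: explicit double loop + manual median of sorted diffs
  hl_oracle <- function(x, y) {
    d <- numeric(0)
    for (xi in x) for (yj in y) d <- c(d, xi - yj)
    d <- sort(d)
    n <- length(d)
    if (n %% 2 == 1) d[(n + 1) / 2] else (d[n / 2] + d[n / 2 + 1]) / 2
  }
  set.seed(42)
  for (rep in 1:200) {
    x <- stats::rnorm(sample(1:20, 1))
    y <- stats::rnorm(sample(1:20, 1))
    expect_identical(hodges_lehmann(x, y), hl_oracle(x, y))
  }

  # antisymmetry and location-shift consistency
  set.seed(1)
  for (rep in 1:20) {
    x <- stats::rnorm(8); y <- stats::rnorm(5); c0 <- stats::runif(1, -5, 5)
    expect_equal(hodges_lehmann(x, y), -hodges_lehmann(y, x))
    expect_equal(hodges_lehmann(x + c0, x), c0)
  }
  expect_error(hodges_lehmann(numeric(0), 1), "non-empty")
})

test_that("welch_u_test reproduces the rank-then-Welch hand computation", {
  # identical multisets: t = 0, p = 1
  r0 <- welch_u_test(c(3, 3, 5), c(3, 5, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # frozen hand computation: ranks {1,2,3} vs {4,5,6}, rank variances 1,
  # t = (2 - 5)/sqrt(1/3 + 1/3), Welch-Satterthwaite df = 4
  r <- welch_u_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * stats::pt(-3 / sqrt(2 / 3), 4),
               tolerance = 1e-12)

  # rank invariance under strictly monotone transforms
  set.seed(2)
  x <- stats::rnorm(9); y <- stats::rnorm(12, 0.5)
  expect_equal(welch_u_test(x, y)$p_value,
               welch_u_test(exp(x), exp(y))$p_value)

  # all pooled values identical
  expect_equal(welch_u_test(c(2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(welch_u_test(1, c(1, 2)), "at least 2")
})

test_that("welch_u_test holds its level under the null", {
  set.seed(11)
  # scaled down from the 2000-replicate statement for runtime; SE of the
  # estimate at 1000 replicates is ~0.007, well inside the [0.03, 0.07] band
  rej <- mean(replicate(1000, {
    welch_u_test(stats::rexp(10), stats::rexp(15))$p_value <= 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("benjamini_hochberg implements the step-up procedure", {
  expect_equal(benjamini_hochberg(0.03)$p_adjusted, 0.03)
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
  expect_equal(bh$p_adjusted, rep(0.04, 4))
  expect_true(all(bh$reject))

  # oracle: stats::p.adjust, plus monotonicity in the sorted order
  set.seed(3)
  for (rep in 1:20) {
    p <- stats::runif(sample(3:12, 1))
    bh <- benjamini_hochberg(p)
    expect_equal(bh$p_adjusted, stats::p.adjust(p, "BH"))
    expect_true(all(diff(bh$p_adjusted[order(p)]) >= -1e-15))
    expect_identical(bh$reject, bh$p_adjusted <= 0.05)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("spearman_cor agrees with the rank-then-Pearson oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, rev(x))$rho, -1)
  expect_equal(spearman_cor(x, x)$p_value, 0)

  # 6 pairs with a tie, vs cor.test's rho
  xt <- c(1, 2, 2, 4, 6, 9)
  yt <- c(3, 1, 4, 4, 8, 7)
  expect_equal(spearman_cor(xt, yt)$rho,
               suppressWarnings(
                 stats::cor.test(xt, yt, method = "spearman")$estimate),
               ignore_attr = TRUE)
  expect_warning(res <- spearman_cor(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$rho))
})

test_that("binomial_test is exact, two-sided and symmetric", {
  expect_equal(binomial_test(50, 100), 1)
  expect_equal(binomial_test(10, 10), 2 / 1024)
  # oracle: stats::binom.test (same minimum-likelihood rule)
  set.seed(4)
  for (rep in 1:25) {
    n <- sample(5:40, 1); k <- sample(0:n, 1)
    p0 <- sample(c(0.3, 0.5, 0.7), 1)
    expect_equal(binomial_test(k, n, p0),
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-12)
    expect_equal(binomial_test(k, n, 0.5), binomial_test(n - k, n, 0.5))
  }
  expect_error(binomial_test(5, 4), "0 <= k <= n")
})

test_that("wilcoxon_rank_sum and pearson_cor match reference computations", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # exact 1-vs-1 enumeration: both orderings equally likely
  expect_equal(wilcoxon_rank_sum(5, 9)$p_value, 1)

  # 5-point samples vs the reference exact distribution
  x <- c(1.2, 3.4, 2.2, 5.1, 0.4)
  y <- c(2.0, 6.3, 4.4, 7.1, 5.9)
  ref <- stats::wilcox.test(x, y, exact = TRUE)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, ref$p.value,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(x, y)$statistic,
               unname(ref$statistic))

  expect_equal(pearson_cor(1:6, 2 * (1:6) + 3), 1)
  expect_equal(pearson_cor(x, y), stats::cor(x, y))
  expect_warning(pc <- pearson_cor(rep(1, 4), 1:4), "constant")
  expect_true(is.na(pc))
})
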