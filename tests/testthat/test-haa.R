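test_that("compute_haa implements the RH-minus-LH definition", {
  rec <- data.frame(fetus_id = c("a", "a", "a", "b"), gw = 18L,
                    target = "eye",
                    hand = c("right", "right", "left", "right"),
                    mt = c(400, 600, 800, 500), tpv = 50)
  coh <- cohort_from_records(rec, c(a = "right", b = "left"))
  h <- compute_haa(coh, "mt", gw = 18, target = "eye")
  expect_equal(nrow(h), 1L)                 # b lacks a left hand: excluded
  expect_equal(attr(h, "n_excluded"), 1L)
  expect_equal(h$haa, -300)
  expect_equal(h$rhaa, 2 * (500 - 800) / 1300, tolerance = 1e-12)
  expect_equal(h$n_rh, 2L)
  expect_equal(h$n_lh, 1L)

  # equal means give exactly zero
  rec2 <- data.frame(fetus_id = "a", gw = 18L, target = "eye",
                     hand = c("right", "left"), mt = c(700, 700), tpv = 50)
  h2 <- compute_haa(cohort_from_records(rec2, c(a = "right")), "mt")
  expect_equal(h2$haa, 0)
  expect_equal(h2$rhaa, 0)

  # sign(rhaa) == sign(haa) for positive metrics, across generated cohorts
  for (s in 1:3) {
    hh <- compute_haa(generate_cohort(synthetic_config(), seed = s), "mt")
    expect_identical(sign(hh$rhaa), sign(hh$haa))
  }
})

test_that("sign_classify follows the metric-specific conventions", {
  expect_identical(sign_classify(c(-300, 200, 0), "mt"),
                   c("right", "left", NA))
  expect_identical(sign_classify(c(-2, 3, 0), "tpv"),
                   c("left", "right", NA))
  # a zero HAA is scored as an error against either label
  acc <- classification_accuracy(sign_classify(0, "mt"), "right")
  expect_equal(acc$accuracy, 0)
})

test_that("classification_accuracy counts exact fractions", {
  expect_equal(classification_accuracy(rep("right", 4),
                                       rep("right", 4))$accuracy, 1)
  pred <- c(rep("right", 24), rep("left", 4))
  labs <- c(rep("right", 24), rep("left", 3), "right")
  expect_equal(classification_accuracy(pred, labs)$accuracy, 27 / 28)
  # inverting binary predictions complements the accuracy
  inv <- ifelse(pred == "right", "left", "right")
  expect_equal(classification_accuracy(inv, labs)$accuracy, 1 - 27 / 28)
})

test_that("permutation p agrees with exhaustive enumeration at small n", {
  # perfectly separated: no permutation can exceed accuracy 1
  haa <- c(-5, -4, -3, 2, 3)
  labels <- c("right", "right", "right", "left", "left")
  res <- permutation_accuracy_test(haa, labels, "mt", n_perm = 500, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_equal(res$p_perm, 0)

  # exhaustive oracle: the label vector's permutation distribution only
  # depends on which positions receive the minority label
  exact_p <- function(haa, labels, metric = "mt") {
    pred <- sign_classify(haa, metric)
    n <- length(labels)
    k <- sum(labels == "left")
    obs <- mean(!is.na(pred) & pred == labels)
    combos <- utils::combn(n, k)
    accs <- apply(combos, 2, function(ix) {
      lab <- rep("right", n); lab[ix] <- "left"
      mean(!is.na(pred) & pred == lab)
    })
    mean(accs > obs + 1e-12)
  }
  set.seed(9)
  for (rep in 1:6) {
    n <- sample(5:7, 1)
    haa <- stats::rnorm(n)
    labels <- sample(c(rep("right", n - 2), rep("left", 2)))
    pe <- exact_p(haa, labels)
    ps <- permutation_accuracy_test(haa, labels, "mt", n_perm = 4000,
                                    seed = rep)$p_perm
    mc_se <- sqrt(pe * (1 - pe) / 4000)
    expect_lte(abs(ps - pe), max(3 * mc_se, 0.01))
  }
})

test_that("permutation p is invariant to which class is called right", {
  set.seed(5)
  haa <- stats::rnorm(10)
  labels <- sample(c(rep("right", 7), rep("left", 3)))
  flipped <- ifelse(labels == "right", "left", "right")
  p1 <- permutation_accuracy_test(haa, labels, "mt", n_perm = 2000,
                                  seed = 3)$p_perm
  # flipping labels AND the metric sign convention mirrors the problem
  p2 <- permutation_accuracy_test(-haa, flipped, "mt", n_perm = 2000,
                                  seed = 3)$p_perm
  expect_equal(p1, p2)
  expect_warning(
    pp <- permutation_accuracy_test(haa, rep("right", 10), "mt",
                                    n_perm = 200, seed = 1),
    "single-class")
  expect_true(is.na(pp$p_perm))
})

test_that("group_haa_separation estimates the between-group displacement", {
  # identical distributions -> estimate 0
  haa <- c(-1, 0, 1, -1, 0, 1)
  labels <- rep(c("right", "left"), each = 3)
  sep <- group_haa_separation(haa, labels)
  expect_equal(sep$estimate, 0)
  # swapped labels negate the estimate
  sep2 <- group_haa_separation(haa, rev(labels))
  expect_equal(sep2$estimate, -sep$estimate)
  expect_error(group_haa_separation(haa, c(rep("right", 5), "left")),
               "at least 2")

  # generator ground truth: groups displaced to -delta and +delta, so the
  # left-minus-right separation is ~2 * 318 ms
  est <- vapply(1:40, function(s) {
    h <- compute_haa(generate_cohort(recovery_config(), seed = 400 + s),
                     "mt", gw = 18, target = "eye")
    group_haa_separation(h$haa, h$handedness)$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 2 * 318), 0.2 * 2 * 318)
})

test_that("silhouette matches the hand-enumerated variant", {
  # clusters {-3,-2} vs {2,3}: s = 0.8, 0.75, 0.75, 0.8
  res <- silhouette_analysis(c(-3, -2, 2, 3),
                             c("right", "right", "left", "left"),
                             n_perm = 200, seed = 1)
  expect_equal(res$s, c(0.8, 0.75, 0.75, 0.8))
  expect_equal(res$mean_s, 0.775)

  # coincident points in opposite clusters have b = 0 -> s = -1
  res2 <- silhouette_analysis(c(0, 0, 5, 0.2),
                              c("right", "left", "left", "right"),
                              n_perm = 100, seed = 1)
  expect_equal(res2$s[1], -1)

  # interleaved clusters from one distribution: with the min-distance
  # between-cluster term, exchangeable data give a NEGATIVE mean
  # silhouette (b is a minimum, a a mean): simulation oracle gives
  # mean -0.725 (SD 0.13) for n = 12; well-separated clusters must beat it
  set.seed(6)
  ms <- replicate(25, {
    silhouette_analysis(stats::rnorm(12),
                        sample(rep(c("right", "left"), 6)),
                        n_perm = 1, seed = 1)$mean_s
  })
  expect_gt(mean(ms), -0.81)
  expect_lt(mean(ms), -0.64)

  expect_warning(
    s1 <- silhouette_analysis(c(1, 2, 3), c("right", "right", "left"),
                              n_perm = 50, seed = 1),
    "singleton")
  expect_equal(s1$s[3], 0)
})

test_that("LOOCV logistic classifies separable data and honors symmetry", {
  # separable 1-D rHAA with a boundary away from 0: intercept handles it
  rhaa <- c(-0.6, -0.5, -0.4, -0.3, 0.4, 0.5, 0.6, 0.7) + 0.1
  labels <- c(rep("right", 4), rep("left", 4))
  res <- loocv_logistic(matrix(rhaa, ncol = 1), labels, n_perm = 0)
  expect_equal(res$accuracy, 1)

  # 2-feature fit on data symmetric about the identity line reproduces the
  # sign rule
  rh <- c(600, 700, 800, 900, 1000, 1100)
  lh <- c(900, 1000, 1100, 600, 700, 800)
  labs <- c(rep("right", 3), rep("left", 3))
  res2 <- loocv_logistic(cbind(rh, lh), labs, n_perm = 0)
  expect_identical(res2$predictions,
                   sign_classify(rh - lh, "mt"))

  # random labels, balanced classes: accuracy hovers near chance
  set.seed(7)
  accs <- replicate(8, {
    f <- stats::rnorm(16)
    loocv_logistic(matrix(f, ncol = 1),
                   sample(rep(c("right", "left"), 8)), n_perm = 0)$accuracy
  })
  expect_gt(mean(accs), 0.2)
  expect_lt(mean(accs), 0.8)
})

test_that("pooled mouth analysis pools weeks and reports exclusions", {
  rec <- expand.grid(fetus_id = c("a", "b", "c", "d"),
                     gw = c(14L, 18L, 22L), hand = c("right", "left"),
                     stringsAsFactors = FALSE)
  rec$target <- "mouth"
  rec$tpv <- 50
  # dominant hand faster by 300 ms for right-handers a,b,c; slower for d
  dom <- with(rec, ifelse(fetus_id == "d", hand == "left", hand == "right"))
  rec$mt <- 1000 + ifelse(dom, -150, 150)
  # fetus c loses its left hand entirely -> excluded, 28-like subset
  rec <- rec[!(rec$fetus_id == "c" & rec$hand == "left"), ]
  coh <- cohort_from_records(
    rec, c(a = "right", b = "right", c = "right", d = "left"))
  pm <- pooled_mouth_analysis(coh, n_perm_sign = 200, n_perm_loocv = 100,
                              seed = 1)
  expect_equal(pm$n_fetuses, 3L)
  expect_equal(pm$n_excluded, 1L)
  expect_equal(pm$sign$accuracy, 1)
  expect_equal(pm$spearman$rho, 1)   # rhaa perfectly orders the coding

  # generator ground truth at the recovery configuration
  accs <- vapply(1:15, function(s) {
    pooled_mouth_analysis(generate_cohort(recovery_config(),
                                          seed = 500 + s),
                          n_perm_sign = 200, n_perm_loocv = 0,
                          seed = s)$sign$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.85)
})

test_that("ties-inclusive permutation p-values are conservatively valid", {
  # direct calibration of the rule itself: random HAA, fixed 25/4 labels,
  # independent by construction. The inclusive rule (P(acc >= obs)) must
  # reject at most ~alpha; the literal strict rule is anti-conservative
  # here (~0.2) because the accuracy distribution has only ~5 atoms.
  set.seed(14)
  labels <- c(rep("right", 25), rep("left", 4))
  rej_incl <- replicate(150, {
    haa <- stats::rnorm(29)
    p <- permutation_accuracy_test(haa, sample(labels), "mt",
                                   n_perm = 400, include_ties = TRUE)$p_perm
    p <= 0.05
  })
  expect_lte(mean(rej_incl), 0.05 + 3 * sqrt(0.05 * 0.95 / 150))
})
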