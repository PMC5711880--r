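test_that("rh_use_proportion divides counts and tests against chance", {
  coh <- tiny_cohort()
  # fetus a: 2 RH + 1 LH; fetus b: 1 RH + 2 LH (all at GW 18)
  ra <- rh_use_proportion(coh, "right", 18)
  expect_equal(ra$proportion, 2 / 3)
  expect_equal(ra$p_value, binomial_test(2, 3))
  rb <- rh_use_proportion(coh, "left", 18)
  expect_equal(rb$proportion, 1 / 3)
  # the two hands' shares sum to 1 within a group-week
  expect_equal(ra$proportion + (ra$n - ra$k) / ra$n, 1)
  # 50/100 -> p = 1 via a constructed cohort
  rec <- data.frame(fetus_id = "a", gw = 18, target = "eye",
                    hand = rep(c("right", "left"), 50), mt = 800, tpv = 50)
  coh50 <- cohort_from_records(rec, c(a = "right"))
  expect_equal(rh_use_proportion(coh50, "right", 18)$p_value, 1)
  # fetus-level variant
  expect_equal(rh_use_proportion(coh, "right", 18, by = "fetuses")$k, 1)
  expect_error(rh_use_proportion(coh, "right", 14), "no movements")
})

test_that("total_movements_by_fetus compares groups' motor activity", {
  coh <- mirrored_cohort()
  res <- total_movements_by_fetus(coh)
  expect_equal(res$p_value, 1)          # identical group totals
  expect_equal(res$group_stats$mean, c(72, 72))
  expect_equal(res$group_stats$sd, c(0, 0))

  # single fetus per group: exact 1-vs-1 enumeration gives p = 1
  rec <- data.frame(fetus_id = c("a", "a", "b"), gw = 18, target = "eye",
                    hand = "right", mt = 800, tpv = 50)
  coh1 <- cohort_from_records(rec, c(a = "right", b = "left"))
  expect_equal(total_movements_by_fetus(coh1)$p_value, 1)
})

test_that("condition comparisons are null-centred, antisymmetric, flagged", {
  coh <- mirrored_cohort()
  cc <- condition_group_comparisons(coh, "mt")
  expect_equal(nrow(cc), 18L)
  expect_true(all(cc$tested))
  expect_true(all(abs(cc$estimate) < 1e-12))
  expect_false(any(cc$significant))

  # swapping the group labels negates estimates and keeps p-values
  coh2 <- generate_cohort(recovery_config(), seed = 5)
  swapped <- coh2
  swapped$fetuses$handedness <-
    ifelse(swapped$fetuses$handedness == "right", "left", "right")
  a <- condition_group_comparisons(coh2, "mt")
  b <- condition_group_comparisons(swapped, "mt")
  tested <- a$tested & b$tested
  expect_equal(b$estimate[tested], -a$estimate[tested], tolerance = 1e-9)
  expect_equal(b$p_raw[tested], a$p_raw[tested], tolerance = 1e-9)

  # a condition with a single left-group movement is skipped, not fatal
  rec <- expand.grid(fetus_id = c("r1", "r2"), gw = 18L, target = "eye",
                     hand = "right", stringsAsFactors = FALSE)
  rec <- rec[rep(1:2, each = 3), ]
  rec$mt <- 800; rec$tpv <- 50
  rec <- rbind(rec, data.frame(fetus_id = "l1", gw = 18L, target = "eye",
                               hand = "right", mt = 900, tpv = 50))
  coh3 <- cohort_from_records(rec, c(r1 = "right", r2 = "right", l1 = "left"))
  cc3 <- condition_group_comparisons(coh3, "mt")
  row <- cc3[cc3$gw == 18 & cc3$target == "eye" & cc3$hand == "right", ]
  expect_false(row$tested)
  expect_equal(row$n_left, 1L)
})

test_that("a dominant-hand MT advantage appears in the right conditions", {
  # generator ground truth: delta = 318 ms at eye/mouth GW >= 18; the
  # right-group-minus-left-group estimate is -delta for RH movements and
  # +delta for LH movements
  est_rh <- est_lh <- est_wall <- numeric(0)
  for (s in 1:30) {
    cc <- condition_group_comparisons(
      generate_cohort(recovery_config(), seed = 100 + s), "mt")
    pick <- function(gw, tg, hd) cc$estimate[cc$gw == gw & cc$target == tg &
                                               cc$hand == hd]
    est_rh <- c(est_rh, pick(18, "eye", "right"), pick(22, "mouth", "right"))
    est_lh <- c(est_lh, pick(18, "eye", "left"), pick(22, "mouth", "left"))
    est_wall <- c(est_wall, pick(18, "wall", "right"))
  }
  expect_lt(abs(mean(est_rh, na.rm = TRUE) + 318), 318 * 0.25)
  expect_lt(abs(mean(est_lh, na.rm = TRUE) - 318), 318 * 0.25)
  expect_lt(abs(mean(est_wall, na.rm = TRUE)), 100)
})

test_that("within-subject correlation reflects the shared fetus offset", {
  # identical per-hand means -> r = 1 everywhere
  coh <- mirrored_cohort()
  w <- within_subject_correlation(coh, "mt")
  expect_true(all(abs(w$by_condition$r - 1) < 1e-12))
  expect_equal(w$median_r, 1)

  # variance-components example: sigma_b = 450, sigma_e = 300,
  # ~4 movements/hand -> median r ~= 0.9 (no handedness effect active)
  cfg <- recovery_config()
  cfg$delta_mt[] <- 0
  cfg$delta_tpv[] <- 0
  med <- vapply(1:40, function(s) {
    within_subject_correlation(generate_cohort(cfg, seed = 200 + s),
                               "mt")$median_r
  }, numeric(1))
  expect_lt(abs(mean(med) - expected_within_subject_r(450, 300, 4)), 0.05)

  # no shared offset and no effect -> correlations scatter around 0
  cfg0 <- recovery_config(sigma_fetus = 1e-6)
  cfg0$delta_mt[] <- 0
  med0 <- vapply(1:25, function(s) {
    within_subject_correlation(generate_cohort(cfg0, seed = 300 + s),
                               "mt")$median_r
  }, numeric(1))
  expect_lt(abs(mean(med0)), 0.15)
})
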