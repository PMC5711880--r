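# Frequency-of-use and distribution analyses: right-hand-use proportions,
# total-movement comparisons between to-be right- and left-handed fetuses,
# the 18 per-condition group comparisons, and within-subject correlations.

metric_values <- function(cohort, metric = c("mt", "tpv")) {
  metric <- match.arg(metric)
  cohort$records[[metric]]
}

#' Right-hand-use proportion with binomial test against chance
#'
#' Fraction of movements performed with the right hand by one handedness
#' group at one gestational week, with an exact two-sided binomial p-value
#' against 0.5. `by = "fetuses"` instead counts fetuses whose individual
#' right-hand-use fraction exceeds one half (exact halves are excluded
#' from the denominator).
#'
#' @param cohort an `fh_cohort`.
#' @param group handedness group, `"right"` or `"left"`.
#' @param gw gestational week (14, 18 or 22).
#' @param by unit of analysis: `"movements"` (default) or `"fetuses"`.
#' @return List with `proportion`, `k`, `n` and `p_value`.
#' @export
rh_use_proportion <- function(cohort, group = c("right", "left"),
                              gw, by = c("movements", "fetuses")) {
  check_cohort(cohort)
  group <- match.arg(group)
  by <- match.arg(by)
  if (!gw %in% GW_LEVELS) stopf("gw must be one of 14, 18, 22")
  sel <- record_handedness(cohort) == group & cohort$records$gw == gw
  if (!any(sel)) stopf("no movements for group '%s' at GW %d", group, gw)
  if (by == "movements") {
    k <- sum(cohort$records$hand[sel] == "right")
    n <- sum(sel)
  } else {
    per <- tapply(cohort$records$hand[sel] == "right",
                  cohort$records$fetus_id[sel], mean)
    per <- per[per != 0.5]
    if (!length(per)) stopf("no fetus with a majority hand at GW %d", gw)
    k <- sum(per > 0.5)
    n <- length(per)
  }
  list(proportion = k / n, k = k, n = n, p_value = binomial_test(k, n, 0.5))
}

#' Total movements per fetus and group comparison
#'
#' Per-fetus total movement counts, group means and SDs, and a two-sided
#' Wilcoxon rank-sum p-value comparing the two handedness groups — the
#' check that any kinematic difference between groups is not an artefact of
#' unequal motor activity sampling.
#'
#' @param cohort an `fh_cohort` containing fetuses of both handedness.
#' @return List with `per_fetus` (data.frame fetus_id, handedness, total),
#'   `group_stats` (group, n, mean, sd) and `p_value`.
#' @export
total_movements_by_fetus <- function(cohort) {
  check_cohort(cohort)
  tot <- table(factor(cohort$records$fetus_id,
                      levels = cohort$fetuses$fetus_id))
  per <- data.frame(fetus_id = cohort$fetuses$fetus_id,
                    handedness = cohort$fetuses$handedness,
                    total = as.integer(tot),
                    stringsAsFactors = FALSE)
  split_tot <- split(per$total, factor(per$handedness, levels = HAND_LEVELS))
  if (any(lengths(split_tot) == 0L)) {
    stopf("both handedness groups must contain at least one fetus")
  }
  gs <- data.frame(
    group = HAND_LEVELS,
    n = lengths(split_tot),
    mean = vapply(split_tot, mean, numeric(1)),
    sd = vapply(split_tot, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  w <- wilcoxon_rank_sum(split_tot$right, split_tot$left)
  list(per_fetus = per, group_stats = gs, p_value = w$p_value)
}

#' Per-condition group comparisons of pooled movement metrics
#'
#' For each of the 18 (week x target x hand) conditions, pools the metric
#' values of all right-handed-group fetuses and all left-handed-group
#' fetuses, estimates the location difference (right-handed group minus
#' left-handed group) with the Hodges-Lehmann estimator, tests it with the
#' Welch U-test, and controls the FDR across the tested conditions with
#' Benjamini-Hochberg. Conditions where either group has fewer than
#' `min_n` movements are reported untested.
#'
#' @param cohort an `fh_cohort`.
#' @param metric `"mt"` (milliseconds) or `"tpv"` (percent of MT).
#' @param q FDR level.
#' @param min_n minimum movements per group for a condition to be tested.
#' @return data.frame with one row per condition: `gw`, `target`, `hand`,
#'   `n_right`, `n_left`, `estimate`, `statistic`, `df`, `p_raw`,
#'   `p_adjusted`, `significant`, `tested`.
#' @export
condition_group_comparisons <- function(cohort, metric = c("mt", "tpv"),
                                        q = 0.05, min_n = 2L) {
  check_cohort(cohort)
  metric <- match.arg(metric)
  vals <- metric_values(cohort, metric)
  grp <- record_handedness(cohort)
  grid <- expand.grid(hand = HAND_LEVELS, target = TARGET_LEVELS,
                      gw = GW_LEVELS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("gw", "target", "hand")]
  res <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- cohort$records$gw == grid$gw[i] &
      cohort$records$target == grid$target[i] &
      cohort$records$hand == grid$hand[i]
    x <- vals[sel & grp == "right"]
    y <- vals[sel & grp == "left"]
    if (length(x) < min_n || length(y) < min_n) {
      return(data.frame(n_right = length(x), n_left = length(y),
                        estimate = NA_real_, statistic = NA_real_,
                        df = NA_real_, p_raw = NA_real_, tested = FALSE))
    }
    w <- welch_u_test(x, y)
    data.frame(n_right = length(x), n_left = length(y),
               estimate = hodges_lehmann(x, y), statistic = w$statistic,
               df = w$df, p_raw = w$p_value, tested = TRUE)
  })
  out <- cbind(grid, do.call(rbind, res))
  out$p_adjusted <- NA_real_
  out$significant <- FALSE
  if (any(out$tested)) {
    bh <- benjamini_hochberg(out$p_raw[out$tested], q)
    out$p_adjusted[out$tested] <- bh$p_adjusted
    out$significant[out$tested] <- bh$reject
  }
  out[, c("gw", "target", "hand", "n_right", "n_left", "estimate",
          "statistic", "df", "p_raw", "p_adjusted", "significant", "tested")]
}

#' Within-subject correlation of right- and left-hand metric means
#'
#' For each (target x week) condition, the Pearson correlation across
#' fetuses between the per-fetus right-hand mean and left-hand mean of the
#' metric, computed over fetuses observed with both hands. High values
#' indicate that overall movement speed is a property of the fetus, shared
#' by both hands — the interdependence that motivates differencing the two
#' hands within each fetus.
#'
#' @param cohort an `fh_cohort`.
#' @param metric `"mt"` or `"tpv"`.
#' @param min_pairs minimum number of both-hand fetuses per condition.
#' @return List with `by_condition` (data.frame gw, target, n, r),
#'   `median_r` and `range_r` over the computed conditions.
#' @export
within_subject_correlation <- function(cohort, metric = c("mt", "tpv"),
                                       min_pairs = 3L) {
  check_cohort(cohort)
  metric <- match.arg(metric)
  vals <- metric_values(cohort, metric)
  rec <- cohort$records
  grid <- expand.grid(target = TARGET_LEVELS, gw = GW_LEVELS,
                      stringsAsFactors = FALSE)[, c("gw", "target")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- rec$gw == grid$gw[i] & rec$target == grid$target[i]
    if (!any(sel)) return(data.frame(n = 0L, r = NA_real_))
    means <- tapply(vals[sel], list(rec$fetus_id[sel], rec$hand[sel]), mean)
    if (!all(c("right", "left") %in% colnames(means))) {
      return(data.frame(n = 0L, r = NA_real_))
    }
    both <- !is.na(means[, "right"]) & !is.na(means[, "left"])
    if (sum(both) < min_pairs) {
      return(data.frame(n = sum(both), r = NA_real_))
    }
    data.frame(n = sum(both),
               r = pearson_cor(means[both, "right"], means[both, "left"]))
  })
  out <- cbind(grid, do.call(rbind, rows))
  r_ok <- out$r[!is.na(out$r)]
  list(by_condition = out,
       median_r = if (length(r_ok)) stats::median(r_ok) else NA_real_,
       range_r = if (length(r_ok)) range(r_ok) else c(NA_real_, NA_real_))
}
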