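# Developmental trajectory of movement time: rank-correlation trend across
# gestational weeks and binned mutual information with the first-order
# Panzeri-Treves small-sample bias correction.

#' Developmental trend of MT for one target
#'
#' Spearman correlation between all pooled MT values towards a target
#' (both hands, both handedness groups) and their gestational week.
#'
#' @param cohort an `fh_cohort`.
#' @param target `"eye"`, `"mouth"` or `"wall"`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
mt_trend <- function(cohort, target = c("eye", "mouth", "wall")) {
  check_cohort(cohort)
  target <- match.arg(target)
  sel <- cohort$records$target == target
  if (sum(sel) < 3L) stopf("need at least 3 movements towards '%s'", target)
  gw <- cohort$records$gw[sel]
  if (length(unique(gw)) < 2L) {
    stopf("single-week data: trend undefined for '%s'", target)
  }
  c(spearman_cor(cohort$records$mt[sel], gw), list(target = target))
}

# Equipopulated bin assignment; ties broken by value order so bins have
# equal counts up to rounding.
quantile_bins <- function(values, n_bins) {
  if (diff(range(values)) == 0) return(rep(1L, length(values)))
  r <- rank(values, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(values)))
}

width_bins <- function(values, n_bins) {
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  b <- findInterval(values, seq(rng[1], rng[2], length.out = n_bins + 1),
                    rightmost.closed = TRUE)
  pmin.int(pmax.int(b, 1L), n_bins)
}

#' Binned mutual information with Panzeri-Treves bias correction
#'
#' Discretises a continuous sample into `n_bins` bins (equipopulated
#' quantile bins by default, the convention of the information-theoretic
#' toolchains used in neuroscience; equal-width bins available) and
#' computes the plug-in mutual information in bits between bin and group
#' from the joint histogram,
#' `I = sum p(b, g) log2( p(b, g) / (p(b) p(g)) )`.
#' The first-order Panzeri-Treves bias estimate,
#' `(1 / (2 N ln 2)) (sum_g (B_g - 1) - (B - 1))` with `B_g` the number of
#' occupied bins within group `g` and `B` the number occupied overall, is
#' subtracted when `correct = TRUE`. The plug-in estimate is biased upward
#' for small samples; the corrected one is approximately unbiased under
#' independence (the bias term can legitimately be negative for strongly
#' dependent data, where the correction then increases the estimate).
#'
#' @param values continuous numeric sample.
#' @param groups discrete labels, same length; at least 2 distinct.
#' @param n_bins number of bins (default 8).
#' @param correct subtract the Panzeri-Treves bias estimate.
#' @param binning `"quantile"` (equipopulated, default) or `"width"`.
#' @return An `fh_mi` list: `mi_plugin`, `bias`, `mi_corrected` (bits),
#'   `n_bins`, `n_samples`.
#' @export
binned_mutual_information <- function(values, groups, n_bins = 8,
                                      correct = TRUE,
                                      binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  n <- length(values)
  if (length(groups) != n) stopf("values and groups must be paired")
  if (n < n_bins) stopf("need at least n_bins samples")
  groups <- as.character(groups)
  if (length(unique(groups)) < 2L) stopf("need at least 2 distinct groups")
  bins <- switch(binning,
                 quantile = quantile_bins(values, n_bins),
                 width = width_bins(values, n_bins))
  joint <- table(bins, groups) / n
  pb <- rowSums(joint)
  pg <- colSums(joint)
  expected <- outer(pb, pg)
  nz <- joint > 0
  mi <- sum(joint[nz] * log2(joint[nz] / expected[nz]))
  b_all <- sum(pb > 0)
  b_g <- apply(joint, 2, function(col) sum(col > 0))
  bias <- (sum(b_g - 1) - (b_all - 1)) / (2 * n * log(2))
  structure(list(mi_plugin = mi,
                 bias = if (correct) bias else 0,
                 mi_corrected = mi - if (correct) bias else 0,
                 n_bins = n_bins, n_samples = n),
            class = "fh_mi")
}

#' Permutation p-value for binned mutual information
#'
#' Shuffles the group labels `n_perm` times and recomputes the
#' (bias-corrected) MI; the p-value is the fraction of shuffles strictly
#' exceeding the observed value.
#'
#' @inheritParams binned_mutual_information
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return List with `mi` (the observed `fh_mi`), `p_perm`, `n_perm`.
#' @export
mi_permutation_test <- function(values, groups, n_bins = 8, n_perm = 10000,
                                seed = NULL,
                                binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  obs <- binned_mutual_information(values, groups, n_bins, correct = TRUE,
                                   binning = binning)
  n <- length(values)
  hits <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      binned_mutual_information(values, groups[sample.int(n)], n_bins,
                                correct = TRUE,
                                binning = binning)$mi_corrected
    }, numeric(1))
  })
  list(mi = obs, p_perm = mean(hits > obs$mi_corrected), n_perm = n_perm)
}

#' Developmental MT analysis for one target
#'
#' Combines the Spearman trend with the binned, bias-corrected mutual
#' information between MT and gestational week, plus its permutation
#' p-value.
#'
#' @param cohort an `fh_cohort`.
#' @param target movement target.
#' @param n_bins MT bins for the MI estimate.
#' @param n_perm label permutations for the MI p-value.
#' @param seed RNG seed.
#' @return List with `trend` (see [mt_trend()]) and `mi`
#'   (see [mi_permutation_test()]).
#' @export
mt_development <- function(cohort, target = c("eye", "mouth", "wall"),
                           n_bins = 8, n_perm = 10000, seed = NULL) {
  target <- match.arg(target)
  trend <- mt_trend(cohort, target)
  sel <- cohort$records$target == target
  mi <- mi_permutation_test(cohort$records$mt[sel],
                            cohort$records$gw[sel],
                            n_bins = n_bins, n_perm = n_perm, seed = seed)
  list(trend = trend, mi = mi, target = target)
}
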