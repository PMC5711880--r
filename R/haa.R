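# Hand-asymmetry advantage (HAA) and handedness inference. The HAA removes
# the strong within-fetus correlation between the two hands by differencing
# them: HAA = RH - LH on the per-fetus condition means, and its relative
# form rHAA = 2(RH - LH)/(RH + LH). Classification then needs only the sign
# of the HAA, plus permutation tests, cluster silhouettes and a
# cross-validated logistic regression for corroboration.

#' Per-fetus hand-asymmetry advantage
#'
#' For every fetus with at least one movement with each hand in a
#' (week, target) condition, the difference between the right-hand and
#' left-hand mean of the metric (`haa = RH - LH`) and its relative form
#' (`rhaa = 2 (RH - LH) / (RH + LH)`). Fetuses lacking one hand in a
#' condition are excluded; the exclusion count is kept as attribute
#' `n_excluded` (not all fetuses perform all movements at all time points).
#'
#' @param cohort an `fh_cohort`.
#' @param metric `"mt"` or `"tpv"`.
#' @param gw,target optional filters (vectors of weeks/targets); default all.
#' @return data.frame with one row per fetus x condition: `fetus_id`,
#'   `handedness`, `gw`, `target`, `metric`, `rh_mean`, `lh_mean`, `n_rh`,
#'   `n_lh`, `haa`, `rhaa`.
#' @export
compute_haa <- function(cohort, metric = c("mt", "tpv"),
                        gw = GW_LEVELS, target = TARGET_LEVELS) {
  check_cohort(cohort)
  metric <- match.arg(metric)
  vals <- metric_values(cohort, metric)
  rec <- cohort$records
  grid <- expand.grid(target = target, gw = gw, stringsAsFactors = FALSE)
  n_excluded <- 0L
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    sel <- rec$gw == grid$gw[i] & rec$target == grid$target[i]
    if (!any(sel)) next
    mean_tab <- tapply(vals[sel], list(rec$fetus_id[sel], rec$hand[sel]), mean)
    count_tab <- table(factor(rec$fetus_id[sel]), factor(rec$hand[sel]))
    for (h in HAND_LEVELS) {
      if (!h %in% colnames(mean_tab)) {
        mean_tab <- cbind(mean_tab, rep(NA_real_, nrow(mean_tab)))
        colnames(mean_tab)[ncol(mean_tab)] <- h
        count_tab <- cbind(count_tab, 0L)
        colnames(count_tab)[ncol(count_tab)] <- h
      }
    }
    ok <- !is.na(mean_tab[, "right"]) & !is.na(mean_tab[, "left"])
    n_excluded <- n_excluded + sum(!ok)
    if (!any(ok)) next
    ids <- rownames(mean_tab)[ok]
    rh <- mean_tab[ok, "right"]
    lh <- mean_tab[ok, "left"]
    rows[[length(rows) + 1L]] <- data.frame(
      fetus_id = ids,
      handedness = cohort$fetuses$handedness[
        match(ids, cohort$fetuses$fetus_id)],
      gw = grid$gw[i], target = grid$target[i], metric = metric,
      rh_mean = unname(rh), lh_mean = unname(lh),
      n_rh = as.integer(count_tab[ids, "right"]),
      n_lh = as.integer(count_tab[ids, "left"]),
      haa = unname(rh - lh),
      rhaa = unname(2 * (rh - lh) / (rh + lh)),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(fetus_id = character(), handedness = character(),
               gw = integer(), target = character(), metric = character(),
               rh_mean = numeric(), lh_mean = numeric(),
               n_rh = integer(), n_lh = integer(),
               haa = numeric(), rhaa = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_excluded = n_excluded)
}

#' Sign-rule handedness prediction from HAA values
#'
#' For MT the dominant hand is the faster one, so a negative HAA
#' (`RH - LH < 0`) predicts right-handedness. For TPV the dominant hand
#' peaks later (shorter deceleration), so a positive HAA predicts
#' right-handedness. A zero HAA yields `NA` and is scored as misclassified
#' whatever the true label (conservative tie policy).
#'
#' @param haa numeric HAA (or rHAA) values.
#' @param metric `"mt"` or `"tpv"`.
#' @return Character vector of `"right"`/`"left"` predictions with `NA`
#'   for ties.
#' @export
sign_classify <- function(haa, metric = c("mt", "tpv")) {
  metric <- match.arg(metric)
  s <- if (metric == "mt") -sign(haa) else sign(haa)
  out <- rep(NA_character_, length(haa))
  out[s > 0] <- "right"
  out[s < 0] <- "left"
  out
}

#' Classification accuracy
#'
#' Fraction of fetuses whose predicted handedness matches the reported
#' postnatal label. `NA` predictions (zero HAA ties) count as errors.
#'
#' @param predictions character vector of `"right"`/`"left"`/`NA`.
#' @param labels true labels, same length.
#' @return List with `accuracy`, `n_correct`, `n_classified`.
#' @export
classification_accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels)) stopf("length mismatch")
  if (!length(labels)) stopf("no classified fetuses")
  correct <- !is.na(predictions) & predictions == labels
  list(accuracy = mean(correct), n_correct = sum(correct),
       n_classified = length(labels))
}

#' Permutation test for sign-rule classification accuracy
#'
#' Shuffles the handedness labels across fetuses uniformly `n_perm` times
#' and recomputes the sign-rule accuracy for each shuffle. The p-value is
#' the fraction of permutations whose accuracy strictly exceeds the
#' observed one (the literal rule; set `smooth = TRUE` for the
#' add-one-smoothed variant `(1 + #{exceed}) / (1 + n_perm)`).
#'
#' With few minority labels the accuracy distribution has only a handful of
#' atoms and the strictly-greater rule is anti-conservative (ties with the
#' observed accuracy are counted as evidence against the null);
#' `include_ties = TRUE` uses `P(accuracy >= observed)`, which is the
#' statistically valid (conservative) variant.
#'
#' @param haa numeric HAA values, one per fetus.
#' @param labels true handedness labels (`"right"`/`"left"`), both classes
#'   present.
#' @param metric `"mt"` or `"tpv"` (fixes the sign convention).
#' @param n_perm number of permutations.
#' @param seed RNG seed for reproducibility.
#' @param smooth use the add-one-smoothed p-value.
#' @param include_ties count permutations tying the observed accuracy in
#'   the p-value (valid variant; default is the literal strict rule).
#' @return List with `accuracy`, `n_classified`, `p_perm`, `n_perm`,
#'   `seed`.
#' @export
permutation_accuracy_test <- function(haa, labels, metric = c("mt", "tpv"),
                                      n_perm = 10000, seed = NULL,
                                      smooth = FALSE, include_ties = FALSE) {
  metric <- match.arg(metric)
  pred <- sign_classify(haa, metric)
  obs <- classification_accuracy(pred, labels)
  if (length(unique(labels)) < 2L) {
    warnf("single-class labels: permutation p undefined")
    return(list(accuracy = obs$accuracy, n_classified = obs$n_classified,
                p_perm = NA_real_, n_perm = n_perm, seed = seed))
  }
  n <- length(labels)
  hits <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      perm <- labels[sample.int(n)]
      mean(!is.na(pred) & pred == perm)
    }, numeric(1))
  })
  exceed <- if (include_ties) hits >= obs$accuracy - 1e-12 else
    hits > obs$accuracy + 1e-12
  p <- if (smooth) (1 + sum(exceed)) / (1 + n_perm) else mean(exceed)
  list(accuracy = obs$accuracy, n_classified = obs$n_classified,
       p_perm = p, n_perm = n_perm, seed = seed)
}

#' Hodges-Lehmann separation of HAA distributions between groups
#'
#' Location difference of the HAA distribution of left-handed fetuses minus
#' that of right-handed fetuses (for MT both groups displace away from zero
#' in opposite directions, so the expected estimate is positive when the
#' effect is present), with a Welch U-test p-value. A more telling effect
#' size than the sign-based accuracy because it uses the magnitudes.
#'
#' @param haa numeric HAA values, one per fetus.
#' @param labels handedness labels, at least 2 fetuses per group.
#' @return List with `estimate` (left minus right, HAA units),
#'   `statistic`, `df`, `p_value`, `n_right`, `n_left`.
#' @export
group_haa_separation <- function(haa, labels) {
  xl <- haa[labels == "left"]
  xr <- haa[labels == "right"]
  if (length(xl) < 2L || length(xr) < 2L) {
    stopf("need at least 2 fetuses per handedness group")
  }
  w <- welch_u_test(xl, xr)
  list(estimate = hodges_lehmann(xl, xr), statistic = w$statistic,
       df = w$df, p_value = w$p_value,
       n_right = length(xr), n_left = length(xl))
}

#' Silhouette analysis of one-dimensional HAA clustering
#'
#' For each fetus `i` with cluster = reported handedness:
#' `a(i)` = mean absolute HAA difference to the other members of its own
#' cluster, `b(i)` = minimum absolute difference to the members of the
#' other cluster (the minimum, not the classical mean), and
#' `s(i) = (b - a) / max(a, b)` in \[-1, 1\]. Values near 1 indicate tight,
#' well-separated clusters. Significance of the mean silhouette is by
#' label permutation with the strictly-greater rule. Points in singleton
#' clusters get `s = 0` with a warning.
#'
#' @param haa numeric HAA values, one per fetus.
#' @param labels handedness labels.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return List with `s` (per fetus), `mean_s`, `p_perm`, `n_perm`.
#' @export
silhouette_analysis <- function(haa, labels, n_perm = 1000, seed = NULL) {
  if (length(unique(labels)) < 2L) stopf("need 2 clusters")
  sil_mean <- function(lab) {
    n <- length(haa)
    s <- numeric(n)
    for (i in seq_len(n)) {
      same <- which(lab == lab[i]); same <- setdiff(same, i)
      other <- which(lab != lab[i])
      if (!length(same)) { s[i] <- 0; next }
      a <- mean(abs(haa[i] - haa[same]))
      b <- min(abs(haa[i] - haa[other]))
      s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }
    s
  }
  s <- sil_mean(labels)
  if (any(table(labels) == 1L)) {
    warnf("singleton cluster: its point(s) get silhouette 0")
  }
  obs <- mean(s)
  n <- length(labels)
  hits <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      mean(sil_mean(labels[sample.int(n)]))
    }, numeric(1))
  })
  list(s = s, mean_s = obs, p_perm = mean(hits > obs), n_perm = n_perm)
}

# Ridge-stabilised logistic fit by Newton iterations on standardised
# features. The tiny penalty is a numerical device to keep the fit finite
# under complete separation (predictions saturate near 0/1); it is not a
# model change.
fit_ridge_logistic <- function(X, y01, lambda = 1e-6, maxit = 100,
                               tol = 1e-8, beta_cap = 30) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, ctr), 2, scl, `/`))
  p <- ncol(Xs)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xs %*% beta)
    prob <- stats::plogis(eta)
    w <- pmax(prob * (1 - prob), 1e-10)
    g <- crossprod(Xs, y01 - prob) - pen %*% beta
    H <- crossprod(Xs, Xs * w) + pen
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + drop(step)
    if (max(abs(step)) < tol || max(abs(beta)) > beta_cap) break
  }
  list(beta = beta, center = ctr, scale = scl)
}

predict_ridge_logistic <- function(fit, xnew) {
  xs <- (as.numeric(xnew) - fit$center) / fit$scale
  stats::plogis(sum(c(1, xs) * fit$beta))
}

#' Leave-one-out cross-validated logistic regression of handedness
#'
#' Each fetus in turn is held out; a logistic model (intercept plus the
#' given features, e.g. the per-fetus RH and LH means, or a 1-D rHAA) is
#' fitted on the remaining fetuses and the held-out handedness is predicted
#' at probability threshold 0.5. Unlike the sign rule, the fitted boundary
#' may depart from the identity line. The permutation p-value repeats the
#' full LOOCV on shuffled labels (strictly-greater rule). Training folds
#' that contain a single class fall back to majority-class prediction.
#'
#' @param features numeric vector or matrix (fetuses x features).
#' @param labels handedness labels, both classes present.
#' @param n_perm number of label permutations (0 skips the test).
#' @param seed RNG seed.
#' @param lambda ridge penalty used to stabilise separated fits.
#' @return List with `accuracy`, `predictions`, `p_perm`, `n_perm`, `seed`.
#' @export
loocv_logistic <- function(features, labels, n_perm = 1000, seed = NULL,
                           lambda = 1e-6) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (length(labels) != n) stopf("length mismatch")
  if (length(unique(labels)) < 2L) stopf("need both classes")
  loocv_acc <- function(lab) {
    y01 <- as.integer(lab == "left")  # model P(left)
    pred <- character(n)
    for (i in seq_len(n)) {
      ytr <- y01[-i]
      if (length(unique(ytr)) == 1L) {
        pred[i] <- if (ytr[1] == 1L) "left" else "right"
        next
      }
      fit <- fit_ridge_logistic(X[-i, , drop = FALSE], ytr, lambda = lambda)
      pred[i] <- if (predict_ridge_logistic(fit, X[i, ]) > 0.5)
        "left" else "right"
    }
    list(acc = mean(pred == lab), pred = pred)
  }
  obs <- loocv_acc(labels)
  p <- NA_real_
  if (n_perm > 0) {
    hits <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        loocv_acc(labels[sample.int(n)])$acc
      }, numeric(1))
    })
    p <- mean(hits > obs$acc)
  }
  list(accuracy = obs$acc, predictions = obs$pred, p_perm = p,
       n_perm = n_perm, seed = seed)
}

#' Pooled mouth-movement analysis across gestational weeks
#'
#' Because mouth MT shows no developmental trend, mouth movements can be
#' pooled over weeks: per fetus, all mouth MT values with each hand are
#' averaged across weeks before forming the rHAA. Fetuses lacking one hand
#' entirely are excluded (with the count reported). Returns the sign-rule
#' accuracy with its permutation p, a 1-D LOOCV logistic accuracy on the
#' rHAA, and the Spearman correlation between rHAA and handedness coded
#' right = -1, left = +1 (so a positive correlation means dominant-hand
#' movements are faster).
#'
#' @param cohort an `fh_cohort`.
#' @param n_perm_sign permutations for the sign-rule test.
#' @param n_perm_loocv permutations for the LOOCV test.
#' @param seed RNG seed (sub-seeds are derived per stage).
#' @return List with `haa_table`, `sign`, `loocv`, `spearman`,
#'   `n_fetuses`, `n_excluded`.
#' @export
pooled_mouth_analysis <- function(cohort, n_perm_sign = 10000,
                                  n_perm_loocv = 1000, seed = NULL) {
  check_cohort(cohort)
  rec <- cohort$records
  sel <- rec$target == "mouth"
  if (!any(sel)) stopf("no mouth movements in cohort")
  means <- tapply(rec$mt[sel], list(rec$fetus_id[sel], rec$hand[sel]), mean)
  for (h in HAND_LEVELS) {
    if (!h %in% colnames(means)) {
      means <- cbind(means, rep(NA_real_, nrow(means)))
      colnames(means)[ncol(means)] <- h
    }
  }
  ok <- !is.na(means[, "right"]) & !is.na(means[, "left"])
  n_excluded <- nrow(cohort$fetuses) - sum(ok)
  if (sum(ok) < 3L) stopf("too few fetuses with both-hand mouth data")
  ids <- rownames(means)[ok]
  labels <- cohort$fetuses$handedness[match(ids, cohort$fetuses$fetus_id)]
  rh <- means[ok, "right"]; lh <- means[ok, "left"]
  rhaa <- unname(2 * (rh - lh) / (rh + lh))
  tab <- data.frame(fetus_id = ids, handedness = labels,
                    rh_mean = unname(rh), lh_mean = unname(lh),
                    rhaa = rhaa, stringsAsFactors = FALSE)
  sign_res <- permutation_accuracy_test(rhaa, labels, metric = "mt",
                                        n_perm = n_perm_sign,
                                        seed = derive_seed(seed, 1))
  loocv_res <- if (length(unique(labels)) == 2L) {
    loocv_logistic(matrix(rhaa, ncol = 1), labels, n_perm = n_perm_loocv,
                   seed = derive_seed(seed, 2))
  } else NULL
  coding <- ifelse(labels == "right", -1, 1)
  sp <- if (length(unique(coding)) == 2L) spearman_cor(rhaa, coding) else
    list(rho = NA_real_, p_value = NA_real_, n = length(rhaa))
  list(haa_table = tab, sign = sign_res, loocv = loocv_res, spearman = sp,
       n_fetuses = length(ids), n_excluded = n_excluded)
}

#' Per-condition HAA inference grid
#'
#' For each (week x target) cell of one metric: the sign-rule accuracy with
#' permutation p-value and the Hodges-Lehmann HAA separation between
#' handedness groups with Welch U-test p-value, with Benjamini-Hochberg
#' adjustment across the tested cells (separately for the two p-value
#' families).
#'
#' @param cohort an `fh_cohort`.
#' @param metric `"mt"` or `"tpv"`.
#' @param n_perm permutations per cell for the accuracy test.
#' @param q FDR level.
#' @param seed RNG seed.
#' @return data.frame with one row per (gw, target) cell.
#' @export
haa_grid <- function(cohort, metric = c("mt", "tpv"), n_perm = 10000,
                     q = 0.05, seed = NULL) {
  metric <- match.arg(metric)
  haa_all <- compute_haa(cohort, metric)
  grid <- expand.grid(target = TARGET_LEVELS, gw = GW_LEVELS,
                      stringsAsFactors = FALSE)[, c("gw", "target")]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    h <- haa_all[haa_all$gw == grid$gw[i] & haa_all$target == grid$target[i], ]
    out <- data.frame(n = nrow(h), n_right = sum(h$handedness == "right"),
                      n_left = sum(h$handedness == "left"),
                      accuracy = NA_real_, p_acc = NA_real_,
                      separation = NA_real_, p_sep = NA_real_)
    if (nrow(h) < 2L) return(out)
    acc <- classification_accuracy(sign_classify(h$haa, metric),
                                   h$handedness)
    out$accuracy <- acc$accuracy
    if (out$n_right >= 1L && out$n_left >= 1L) {
      out$p_acc <- permutation_accuracy_test(
        h$haa, h$handedness, metric, n_perm = n_perm,
        seed = derive_seed(seed, i))$p_perm
    }
    if (out$n_right >= 2L && out$n_left >= 2L) {
      sep <- group_haa_separation(h$haa, h$handedness)
      out$separation <- sep$estimate
      out$p_sep <- sep$p_value
    }
    out
  })
  out <- cbind(grid, metric = metric, do.call(rbind, rows))
  for (col in c("p_acc", "p_sep")) {
    adj <- rep(NA_real_, nrow(out))
    sig <- rep(FALSE, nrow(out))
    tested <- !is.na(out[[col]])
    if (any(tested)) {
      bh <- benjamini_hochberg(out[[col]][tested], q)
      adj[tested] <- bh$p_adjusted
      sig[tested] <- bh$reject
    }
    out[[paste0(col, "_adj")]] <- adj
    out[[paste0(col, "_sig")]] <- sig
  }
  out
}
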