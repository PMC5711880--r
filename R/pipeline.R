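# End-to-end orchestration: counts and summaries, hand-use proportions,
# per-condition comparisons, HAA inference grids, pooled-mouth analysis and
# developmental MT analysis, with deterministic per-stage seeds and a tidy
# CSV + JSON report bundle.

#' Analysis run configuration
#'
#' @param n_perm_sign permutations for sign-rule accuracy tests.
#' @param n_perm_loocv permutations for LOOCV logistic tests.
#' @param n_perm_silhouette permutations for silhouette tests.
#' @param n_perm_mi permutations for the MI significance test.
#' @param q FDR level for Benjamini-Hochberg adjustment.
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return A validated list of class `fh_run_config`.
#' @export
run_config <- function(n_perm_sign = 10000, n_perm_loocv = 1000,
                       n_perm_silhouette = 1000, n_perm_mi = 10000,
                       q = 0.05, seed = 1L) {
  for (nm in c("n_perm_sign", "n_perm_loocv", "n_perm_silhouette",
               "n_perm_mi")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 100) stopf("`%s` must be >= 100", nm)
  }
  check_prob(q, "q")
  structure(list(n_perm_sign = as.integer(n_perm_sign),
                 n_perm_loocv = as.integer(n_perm_loocv),
                 n_perm_silhouette = as.integer(n_perm_silhouette),
                 n_perm_mi = as.integer(n_perm_mi),
                 q = q, seed = as.integer(seed)),
            class = "fh_run_config")
}

#' Run the full handedness-inference analysis
#'
#' Sequences every pipeline stage on one cohort: (1) movement counts and
#' group summaries, (2) right-hand-use proportions with binomial tests,
#' (3) the 18 per-condition group comparisons for MT and TPV, (4) the
#' per-condition HAA accuracy / separation grid for both metrics, (5) the
#' Spearman / LOOCV / silhouette grid for MT, (6) the pooled-mouth
#' analysis, and (7) the developmental trend and mutual information per
#' target. Deterministic given (cohort, config): every stage derives its
#' seed from `config$seed`.
#'
#' @param cohort an `fh_cohort`.
#' @param config an `fh_run_config`.
#' @param out_dir optional directory; when given, each stage is written as
#'   a tidy CSV plus a `manifest.json` echoing the configuration.
#' @return A named list (the report bundle) with elements `counts`,
#'   `group_summary`, `rh_use`, `comparisons_mt`, `comparisons_tpv`,
#'   `haa_grid_mt`, `haa_grid_tpv`, `inference_grid_mt`, `pooled_mouth`,
#'   `development`, `exclusions` and `config`.
#' @export
run_full_analysis <- function(cohort, config = run_config(),
                              out_dir = NULL) {
  check_cohort(cohort)
  stopifnot(inherits(config, "fh_run_config"))
  seed <- config$seed
  counts <- counts_table(cohort)
  n_right <- sum(cohort$fetuses$handedness == "right")
  n_left <- sum(cohort$fetuses$handedness == "left")
  summary <- group_movement_summary(counts, max(n_right, 1L), max(n_left, 1L))

  rh_use <- do.call(rbind, lapply(GW_LEVELS, function(w) {
    do.call(rbind, lapply(HAND_LEVELS, function(g) {
      res <- tryCatch(rh_use_proportion(cohort, g, w),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(group = g, gw = w, proportion = res$proportion,
                 k = res$k, n = res$n, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    }))
  }))

  comparisons <- lapply(c(mt = "mt", tpv = "tpv"), function(m) {
    condition_group_comparisons(cohort, m, q = config$q)
  })

  grids <- lapply(c(mt = "mt", tpv = "tpv"), function(m) {
    haa_grid(cohort, m, n_perm = config$n_perm_sign, q = config$q,
             seed = derive_seed(seed, if (m == "mt") 10 else 20))
  })

  # Spearman / LOOCV / silhouette grid on MT HAA per (gw, target)
  haa_mt <- compute_haa(cohort, "mt")
  cells <- expand.grid(target = TARGET_LEVELS, gw = GW_LEVELS,
                       stringsAsFactors = FALSE)[, c("gw", "target")]
  inference <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    h <- haa_mt[haa_mt$gw == cells$gw[i] & haa_mt$target == cells$target[i], ]
    out <- data.frame(gw = cells$gw[i], target = cells$target[i],
                      n = nrow(h), spearman_rho = NA_real_,
                      spearman_p = NA_real_, loocv_accuracy = NA_real_,
                      loocv_p = NA_real_, silhouette = NA_real_,
                      silhouette_p = NA_real_, stringsAsFactors = FALSE)
    if (nrow(h) < 4L || length(unique(h$handedness)) < 2L) return(out)
    coding <- ifelse(h$handedness == "right", -1, 1)
    sp <- spearman_cor(h$haa, coding)
    out$spearman_rho <- sp$rho
    out$spearman_p <- sp$p_value
    lo <- loocv_logistic(cbind(h$rh_mean, h$lh_mean), h$handedness,
                         n_perm = config$n_perm_loocv,
                         seed = derive_seed(seed, 30 + i))
    out$loocv_accuracy <- lo$accuracy
    out$loocv_p <- lo$p_perm
    if (min(table(h$handedness)) >= 2L) {
      sil <- silhouette_analysis(h$haa, h$handedness,
                                 n_perm = config$n_perm_silhouette,
                                 seed = derive_seed(seed, 40 + i))
      out$silhouette <- sil$mean_s
      out$silhouette_p <- sil$p_perm
    }
    out
  }))

  pooled <- tryCatch(
    pooled_mouth_analysis(cohort, n_perm_sign = config$n_perm_sign,
                          n_perm_loocv = config$n_perm_loocv,
                          seed = derive_seed(seed, 50)),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "fh_stage_error"))

  development <- do.call(rbind, lapply(seq_along(TARGET_LEVELS), function(i) {
    tg <- TARGET_LEVELS[i]
    res <- tryCatch(
      mt_development(cohort, tg, n_perm = config$n_perm_mi,
                     seed = derive_seed(seed, 60 + i)),
      error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(target = tg, spearman_rho = res$trend$rho,
               spearman_p = res$trend$p_value, n = res$trend$n,
               mi_plugin = res$mi$mi$mi_plugin, mi_bias = res$mi$mi$bias,
               mi_corrected = res$mi$mi$mi_corrected,
               mi_p = res$mi$p_perm, stringsAsFactors = FALSE)
  }))

  bundle <- list(
    counts = counts, group_summary = summary, rh_use = rh_use,
    comparisons_mt = comparisons$mt, comparisons_tpv = comparisons$tpv,
    haa_grid_mt = grids$mt, haa_grid_tpv = grids$tpv,
    inference_grid_mt = inference, pooled_mouth = pooled,
    development = development,
    exclusions = list(haa_mt_excluded = attr(haa_mt, "n_excluded")),
    config = config
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (is.data.frame(x)) {
      utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(as.data.frame(bundle$counts), "counts")
  wr(bundle$group_summary, "group_summary")
  wr(bundle$rh_use, "rh_use")
  wr(bundle$comparisons_mt, "comparisons_mt")
  wr(bundle$comparisons_tpv, "comparisons_tpv")
  wr(bundle$haa_grid_mt, "haa_grid_mt")
  wr(bundle$haa_grid_tpv, "haa_grid_tpv")
  wr(bundle$inference_grid_mt, "inference_grid_mt")
  wr(bundle$development, "development")
  if (!inherits(bundle$pooled_mouth, "fh_stage_error")) {
    wr(bundle$pooled_mouth$haa_table, "pooled_mouth_haa")
  }
  manifest <- list(
    config = unclass(bundle$config),
    n_fetuses = nrow(bundle$counts) * 0 + sum(bundle$group_summary$n_fetuses),
    grand_total = attr(bundle$counts, "grand_total"),
    exclusions = bundle$exclusions,
    pooled_mouth = if (inherits(bundle$pooled_mouth, "fh_stage_error"))
      list(error = bundle$pooled_mouth$message)
    else list(n_fetuses = bundle$pooled_mouth$n_fetuses,
              n_excluded = bundle$pooled_mouth$n_excluded,
              sign_accuracy = bundle$pooled_mouth$sign$accuracy,
              sign_p = bundle$pooled_mouth$sign$p_perm,
              loocv_accuracy = bundle$pooled_mouth$loocv$accuracy %||% NA,
              spearman_rho = bundle$pooled_mouth$spearman$rho)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
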