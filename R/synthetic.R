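# Synthetic cohort generator. The model is the stated statistical world of
# the analysis: a shared per-fetus speed offset (which induces the high
# within-subject RH/LH correlation), an additive dominant-hand advantage
# split symmetrically between hands, Poisson movement counts calibrated to
# the published hand-by-week marginals, and Gaussian residuals with a floor
# that injects mild non-normality.

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the cohort structure the analysis was designed for:
#' 29 fetuses of whom 25/29 become right-handed; movement counts whose
#' group-by-week expectations match the published counts table; a
#' dominant-hand MT advantage of 318 ms for eye and mouth targets from
#' gestational week 18; a dominant-hand TPV advantage of 2.1 percentage
#' points for the same conditions; a between-fetus SD of 450 ms against a
#' within-fetus residual SD of 300 ms (which yields the reported high
#' within-subject RH/LH correlation at ~4 movements per hand); and
#' right-hand-use probabilities above/below one half for the two groups.
#' Baseline per-target MT means are implementer defaults (no per-target
#' means are published): eye rises 900/1100/1300 ms across weeks so the
#' eye target shows a developmental trend, mouth and wall are flat.
#'
#' @param n_fetuses number of fetuses.
#' @param p_right probability a fetus becomes right-handed.
#' @param mu_mt 3x3 matrix (targets x weeks) of baseline MT means, ms.
#' @param delta_mt matching matrix of dominant-hand MT advantages, ms.
#' @param mu_tpv 3x3 matrix of baseline TPV means, percent.
#' @param delta_tpv matching matrix of dominant-hand TPV advantages,
#'   percentage points.
#' @param sigma_fetus between-fetus SD of the shared MT offset, ms.
#' @param sigma_resid within-fetus movement-to-movement MT SD, ms.
#' @param sigma_tpv TPV residual SD, percentage points.
#' @param rh_use_prob 2x3 matrix (groups right/left x weeks) of
#'   right-hand-use probabilities.
#' @param movements_per_fetus_week mean movement count per fetus per week
#'   (length 3); defaults match the published week totals in expectation.
#' @param mt_floor lower truncation for MT, ms.
#' @param lognormal_resid use multiplicative lognormal MT residuals
#'   instead of additive Gaussian ones (same coefficient of variation).
#' @param handedness_assignment `"fixed"` (default) draws exactly
#'   `round(n_fetuses * p_right)` right-handers in random roster positions,
#'   emulating the fixed 25/4 composition of the cohort this generator
#'   models; `"bernoulli"` draws each fetus independently. The fixed
#'   composition keeps the label-permutation tests near their nominal
#'   level, which independent draws destroy whenever they produce only
#'   1-3 left-handers (the strictly-greater permutation rule is then
#'   sharply anti-conservative).
#' @param seed default RNG seed for [generate_cohort()].
#' @return A validated list of class `fh_synth_config`.
#' @export
synthetic_config <- function(n_fetuses = 29L,
                             p_right = 25 / 29,
                             mu_mt = NULL,
                             delta_mt = NULL,
                             mu_tpv = NULL,
                             delta_tpv = NULL,
                             sigma_fetus = 450,
                             sigma_resid = 300,
                             sigma_tpv = 5,
                             rh_use_prob = NULL,
                             movements_per_fetus_week = NULL,
                             mt_floor = 200,
                             lognormal_resid = FALSE,
                             handedness_assignment = c("fixed", "bernoulli"),
                             seed = NULL) {
  handedness_assignment <- match.arg(handedness_assignment)
  dimn <- list(TARGET_LEVELS, as.character(GW_LEVELS))
  mat3 <- function(x) matrix(x, 3, 3, byrow = TRUE, dimnames = dimn)
  mu_mt <- mu_mt %||% mat3(c(900, 1100, 1300,    # eye: developmental rise
                             1000, 1000, 1000,   # mouth: flat
                             800, 800, 800))     # wall: flat
  delta_mt <- delta_mt %||% mat3(c(0, 318, 318,
                                   0, 318, 318,
                                   0, 0, 0))
  mu_tpv <- mu_tpv %||% mat3(c(40, 40, 40,
                               45, 45, 45,
                               55, 55, 55))
  delta_tpv <- delta_tpv %||% mat3(c(0, 2.1, 2.1,
                                     0, 2.1, 2.1,
                                     0, 0, 0))
  rh_use_prob <- rh_use_prob %||% matrix(
    c(0.55, 0.60, 0.60,
      0.50, 0.45, 0.45), 2, 3, byrow = TRUE,
    dimnames = list(HAND_LEVELS, as.character(GW_LEVELS)))
  # week totals of the published counts table divided by 29 fetuses
  movements_per_fetus_week <- movements_per_fetus_week %||%
    c(`14` = 139 / 29, `18` = 164 / 29, `22` = 185 / 29)
  cfg <- list(n_fetuses = as.integer(n_fetuses), p_right = p_right,
              mu_mt = mu_mt, delta_mt = delta_mt, mu_tpv = mu_tpv,
              delta_tpv = delta_tpv, sigma_fetus = sigma_fetus,
              sigma_resid = sigma_resid, sigma_tpv = sigma_tpv,
              rh_use_prob = rh_use_prob,
              movements_per_fetus_week = movements_per_fetus_week,
              mt_floor = mt_floor, lognormal_resid = lognormal_resid,
              handedness_assignment = handedness_assignment,
              seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "fh_synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_fetuses < 1L) stopf("n_fetuses must be >= 1")
  check_prob(cfg$p_right, "p_right")
  check_prob(as.vector(cfg$rh_use_prob), "rh_use_prob")
  if (any(cfg$mu_mt <= 0)) stopf("mu_mt must be > 0")
  for (nm in c("sigma_fetus", "sigma_resid", "sigma_tpv")) {
    if (cfg[[nm]] <= 0) stopf("`%s` must be > 0", nm)
  }
  if (any(cfg$delta_mt < 0) || any(cfg$delta_tpv < 0)) {
    stopf("advantages must be >= 0 (the dominant hand is faster by design)")
  }
  if (any(cfg$movements_per_fetus_week <= 0)) {
    stopf("movements_per_fetus_week must be > 0")
  }
  invisible(cfg)
}

#' Generate a synthetic movement cohort
#'
#' Draws handedness per fetus (`Bernoulli(p_right)`), a shared per-fetus
#' MT offset (`Normal(0, sigma_fetus^2)` applied to both hands, all targets
#' and weeks), Poisson movement counts per fetus-week, uniform targets,
#' hand choice from the group/week right-hand-use probability, and then
#' `MT = mu + offset -/+ delta/2 + residual` (minus for the dominant hand,
#' plus for the non-dominant, so the condition mean is unaffected by the
#' handedness composition and the asymmetry lands entirely in the HAA),
#' truncated below at `mt_floor`. TPV is analogous with `+ delta_tpv/2`
#' for the dominant hand, clipped to (1, 99).
#'
#' @param config an `fh_synth_config`.
#' @param seed RNG seed (defaults to `config$seed`); identical seeds give
#'   identical cohorts.
#' @return An `fh_cohort` with attributes `n_truncated` and `n_clipped`
#'   (numbers of floored MT / clipped TPV values) and `config`.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            seed = config$seed) {
  validate_synth_config(config)
  with_seed(seed, {
    n <- config$n_fetuses
    ids <- sprintf("f%02d", seq_len(n))
    handed <- if (identical(config$handedness_assignment, "bernoulli")) {
      ifelse(stats::rbinom(n, 1, config$p_right) == 1, "right", "left")
    } else {
      n_right <- max(1L, min(n - 1L, round(n * config$p_right)))
      sample(rep(c("right", "left"), c(n_right, n - n_right)))
    }
    offset <- stats::rnorm(n, 0, config$sigma_fetus)
    rows <- vector("list", n * 3L)
    k <- 0L
    for (i in seq_len(n)) {
      for (w in seq_along(GW_LEVELS)) {
        m <- stats::rpois(1, config$movements_per_fetus_week[w])
        if (m == 0L) next
        target <- sample(TARGET_LEVELS, m, replace = TRUE)
        p_rh <- config$rh_use_prob[handed[i], w]
        hand <- ifelse(stats::rbinom(m, 1, p_rh) == 1, "right", "left")
        dominant <- hand == handed[i]
        ti <- match(target, TARGET_LEVELS)
        mu <- config$mu_mt[cbind(ti, w)]
        shift <- ifelse(dominant, -1, 1) * config$delta_mt[cbind(ti, w)] / 2
        base <- mu + offset[i] + shift
        mt <- if (config$lognormal_resid) {
          cv <- config$sigma_resid / mu
          base * stats::rlnorm(m, -log1p(cv^2) / 2, sqrt(log1p(cv^2)))
        } else {
          base + stats::rnorm(m, 0, config$sigma_resid)
        }
        tshift <- ifelse(dominant, 1, -1) * config$delta_tpv[cbind(ti, w)] / 2
        tpv <- config$mu_tpv[cbind(ti, w)] + tshift +
          stats::rnorm(m, 0, config$sigma_tpv)
        k <- k + 1L
        rows[[k]] <- data.frame(fetus_id = ids[i], gw = GW_LEVELS[w],
                                target = target, hand = hand,
                                mt = mt, tpv = tpv,
                                stringsAsFactors = FALSE)
      }
    }
    rec <- do.call(rbind, rows[seq_len(k)])
    n_trunc <- sum(rec$mt < config$mt_floor)
    rec$mt <- pmax(rec$mt, config$mt_floor)
    n_clip <- sum(rec$tpv <= 1 | rec$tpv >= 99)
    rec$tpv <- pmin(pmax(rec$tpv, 1 + 1e-6), 99)
    coh <- cohort(data.frame(fetus_id = ids, handedness = handed,
                             stringsAsFactors = FALSE), rec)
    attr(coh, "n_truncated") <- n_trunc
    attr(coh, "n_clipped") <- n_clip
    attr(coh, "config") <- config
    coh
  })
}

#' Generate a null cohort (no handedness effect)
#'
#' As [generate_cohort()] but with every dominant-hand advantage forced to
#' zero and all right-hand-use probabilities forced to one half: the
#' type-I-error harness for the whole pipeline.
#'
#' @inheritParams generate_cohort
#' @return An `fh_cohort`.
#' @export
generate_null_cohort <- function(config = synthetic_config(),
                                 seed = config$seed) {
  config$delta_mt[] <- 0
  config$delta_tpv[] <- 0
  config$rh_use_prob[] <- 0.5
  generate_cohort(config, seed)
}

#' Generate a synthetic 2-D trajectory with known MT and TPV
#'
#' Builds a straight-line movement whose true speed profile is triangular:
#' zero until onset, linear rise to the peak at `tpv_pct`% of `mt_ms`,
#' linear fall back to zero at `mt_ms`, with stationary lead-in/lead-out
#' samples, sampled at the ultrasound frame rate (4 Hz). On the noiseless
#' output, [trajectory_metrics()] recovers MT within one sample period and
#' TPV within the corresponding percentage bound.
#'
#' @param mt_ms true movement time, ms (> 500 so at least 3 samples fall
#'   inside the movement at 4 Hz).
#' @param tpv_pct true time-to-peak-velocity, percent of MT, in (0, 100).
#' @param seed RNG seed for the positional jitter.
#' @param jitter_sd SD of positional jitter, intraocular units (0 = none).
#' @param rate_hz sampling rate.
#' @param lead stationary samples before onset and after offset.
#' @param distance total path length, intraocular units.
#' @return An `fh_trajectory`.
#' @export
generate_trajectory <- function(mt_ms, tpv_pct, seed = NULL,
                                jitter_sd = 0, rate_hz = 4, lead = 3L,
                                distance = 2) {
  if (mt_ms <= 500) stopf("mt_ms must exceed 500 ms at 4 Hz sampling")
  if (tpv_pct <= 0 || tpv_pct >= 100) stopf("tpv_pct must be in (0, 100)")
  dt <- 1 / rate_hz
  mt_s <- mt_ms / 1000
  t0 <- lead * dt
  t_peak <- t0 + tpv_pct / 100 * mt_s
  t_end <- t0 + mt_s
  v_peak <- 2 * distance / mt_s  # triangle area = distance
  times <- seq(0, t_end + lead * dt, by = dt)
  # closed-form arc length of the triangular speed profile
  pos_x <- vapply(times, function(t) {
    if (t <= t0) return(0)
    if (t >= t_end) return(distance)
    if (t <= t_peak) {
      0.5 * v_peak * (t - t0)^2 / (t_peak - t0)
    } else {
      d_rise <- 0.5 * v_peak * (t_peak - t0)
      d_rise + v_peak * (t - t_peak) -
        0.5 * v_peak * (t - t_peak)^2 / (t_end - t_peak)
    }
  }, numeric(1))
  pos <- cbind(pos_x, 0)
  if (jitter_sd > 0) {
    pos <- pos + with_seed(seed, {
      matrix(stats::rnorm(2 * length(times), 0, jitter_sd),
             ncol = 2)
    })
  }
  trajectory(times, pos, calibration_length = 1)
}

#' Closed-form expected within-subject RH/LH correlation
#'
#' Variance-components prediction for the Pearson correlation between
#' per-fetus right-hand and left-hand means under the generator model:
#' `r = sigma_b^2 / sqrt((sigma_b^2 + sigma_e^2/m_rh)(sigma_b^2 +
#' sigma_e^2/m_lh))`, where `m_rh`/`m_lh` are the (harmonic-mean) numbers
#' of movements averaged per hand. When a dominant-hand advantage `delta`
#' is active in the condition, the +/- delta/2 displacement adds a
#' variance component `v_h = (delta^2/4) var(h)` (with `h = +/-1` the
#' handedness coding, so `var(h) = 1 - mean(h)^2`) to each hand mean and
#' an equal negative covariance between them, which the full form accounts
#' for.
#'
#' @param sigma_fetus between-fetus SD.
#' @param sigma_resid residual SD.
#' @param m_rh,m_lh movements averaged per hand (scalars; for unequal
#'   per-fetus counts pass the harmonic mean `1 / mean(1/m)`).
#' @param delta dominant-hand advantage active in the condition (same
#'   units as the metric; 0 for none).
#' @param handed_var variance of the +/-1 handedness coding across the
#'   fetuses entering the correlation (`1 - mean(h)^2`).
#' @return Predicted correlation.
#' @export
expected_within_subject_r <- function(sigma_fetus, sigma_resid,
                                      m_rh, m_lh = m_rh,
                                      delta = 0, handed_var = 0) {
  vb <- sigma_fetus^2
  vh <- delta^2 / 4 * handed_var
  (vb - vh) / sqrt((vb + vh + sigma_resid^2 / m_rh) *
                     (vb + vh + sigma_resid^2 / m_lh))
}
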