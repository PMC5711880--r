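# Shared fixtures: everything is built in code at test time.

# Two-fetus, hand-built cohort with known arithmetic.
tiny_cohort <- function() {
  cohort(
    fetuses = data.frame(fetus_id = c("a", "b"),
                         handedness = c("right", "left"),
                         stringsAsFactors = FALSE),
    records = data.frame(
      fetus_id = c("a", "a", "a", "b", "b", "b"),
      gw = c(18, 18, 18, 18, 18, 18),
      target = "eye",
      hand = c("right", "right", "left", "right", "left", "left"),
      mt = c(400, 600, 800, 900, 500, 700),
      tpv = c(40, 45, 50, 42, 55, 60),
      stringsAsFactors = FALSE)
  )
}

# Generator configuration of the parameter-recovery world:
# ~4 movements per hand per (target, week) condition.
recovery_config <- function(...) {
  synthetic_config(movements_per_fetus_week = c(24, 24, 24), ...)
}

# Build a cohort from a records data.frame, deriving the roster.
cohort_from_records <- function(records, handedness_map) {
  ids <- unique(records$fetus_id)
  cohort(
    fetuses = data.frame(fetus_id = ids,
                         handedness = unname(handedness_map[ids]),
                         stringsAsFactors = FALSE),
    records = records
  )
}

# A balanced cohort where each group has the same metric values in every
# condition (null with exactly mirrored distributions).
mirrored_cohort <- function(n_per_group = 3, values = c(700, 800, 900, 1000)) {
  ids <- c(sprintf("r%d", seq_len(n_per_group)),
           sprintf("l%d", seq_len(n_per_group)))
  handed <- rep(c("right", "left"), each = n_per_group)
  # per-fetus speed offsets, identical for the two hands and paired
  # across the two groups so group distributions coincide exactly
  offsets <- stats::setNames(rep(100 * (seq_len(n_per_group) - 1), 2), ids)
  grid <- expand.grid(fetus_id = ids, gw = c(14L, 18L, 22L),
                      target = c("eye", "mouth", "wall"),
                      hand = c("right", "left"),
                      stringsAsFactors = FALSE)
  records <- grid[rep(seq_len(nrow(grid)), each = length(values)), ]
  records$mt <- rep(values, nrow(grid)) + offsets[records$fetus_id]
  records$tpv <- 50
  cohort(data.frame(fetus_id = ids, handedness = handed,
                    stringsAsFactors = FALSE), records)
}
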