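#' Assemble and validate a fetal-movement cohort
#'
#' A cohort couples a fetus roster (one row per fetus, with the postnatal
#' handedness label assigned at age 9) with per-movement kinematic records:
#' gestational week (14, 18 or 22), target (`eye`, `mouth`, `wall`), moving
#' hand, movement time MT (milliseconds) and time-to-peak-velocity TPV
#' (percent of MT).
#'
#' @param fetuses data.frame with columns `fetus_id` (unique) and
#'   `handedness` (`"right"` or `"left"`).
#' @param records data.frame with columns `fetus_id`, `gw`, `target`,
#'   `hand`, `mt` (ms, > 0) and `tpv` (percent, in (0, 100)).
#' @return An object of class `fh_cohort`: a list with elements `fetuses`
#'   and `records` (validated data.frames).
#' @examples
#' coh <- cohort(
#'   fetuses = data.frame(fetus_id = "f1", handedness = "right"),
#'   records = data.frame(fetus_id = "f1", gw = 18, target = "eye",
#'                        hand = "right", mt = 950, tpv = 42)
#' )
#' @export
cohort <- function(fetuses, records) {
  problems <- validate_cohort_tables(fetuses, records)
  if (length(problems)) {
    stopf("invalid cohort:\n%s", paste("-", problems, collapse = "\n"))
  }
  fetuses <- data.frame(
    fetus_id = as.character(fetuses$fetus_id),
    handedness = as.character(fetuses$handedness),
    stringsAsFactors = FALSE
  )
  records <- data.frame(
    fetus_id = as.character(records$fetus_id),
    gw = as.integer(records$gw),
    target = as.character(records$target),
    hand = as.character(records$hand),
    mt = as.numeric(records$mt),
    tpv = as.numeric(records$tpv),
    stringsAsFactors = FALSE
  )
  structure(list(fetuses = fetuses, records = records), class = "fh_cohort")
}

# Returns a character vector of problems (empty when valid). Row indices in
# messages refer to the rows of `records`.
validate_cohort_tables <- function(fetuses, records) {
  problems <- character()
  need_f <- c("fetus_id", "handedness")
  need_r <- c("fetus_id", "gw", "target", "hand", "mt", "tpv")
  if (!is.data.frame(fetuses) || !all(need_f %in% names(fetuses))) {
    return(sprintf("fetus roster must have columns %s",
                   paste(need_f, collapse = ", ")))
  }
  if (!is.data.frame(records) || !all(need_r %in% names(records))) {
    return(sprintf("records must have columns %s",
                   paste(need_r, collapse = ", ")))
  }
  if (nrow(fetuses) < 1L) problems <- c(problems, "empty cohort: no fetuses")
  if (anyDuplicated(fetuses$fetus_id)) {
    problems <- c(problems, "duplicate fetus_id in roster")
  }
  bad_h <- !fetuses$handedness %in% HAND_LEVELS
  if (any(bad_h)) {
    problems <- c(problems, sprintf(
      "invalid handedness for fetus %s",
      paste(fetuses$fetus_id[bad_h], collapse = ", ")))
  }
  row_flag <- function(bad, what) {
    if (any(bad)) sprintf("%s in record row(s) %s", what,
                          paste(which(bad), collapse = ", "))
  }
  problems <- c(
    problems,
    row_flag(!records$fetus_id %in% fetuses$fetus_id, "unknown fetus_id"),
    row_flag(!records$gw %in% GW_LEVELS, "gw not in {14, 18, 22}"),
    row_flag(!records$target %in% TARGET_LEVELS, "invalid target"),
    row_flag(!records$hand %in% HAND_LEVELS, "invalid hand"),
    row_flag(!is.finite(as.numeric(records$mt)) |
               as.numeric(records$mt) <= 0, "mt must be > 0"),
    row_flag(!is.finite(as.numeric(records$tpv)) |
               as.numeric(records$tpv) <= 0 |
               as.numeric(records$tpv) >= 100, "tpv must be in (0, 100)")
  )
  problems[!vapply(problems, is.null, logical(1))]
}

#' @export
print.fh_cohort <- function(x, ...) {
  n_right <- sum(x$fetuses$handedness == "right")
  cat(sprintf(
    "<fh_cohort> %d fetuses (%d right-handed, %d left-handed), %d movements\n",
    nrow(x$fetuses), n_right, nrow(x$fetuses) - n_right, nrow(x$records)))
  invisible(x)
}

is_cohort <- function(x) inherits(x, "fh_cohort")

check_cohort <- function(x) {
  if (!is_cohort(x)) stopf("expected an `fh_cohort` (see `cohort()`)")
  invisible(x)
}

# handedness label per record, joined from the roster
record_handedness <- function(cohort) {
  cohort$fetuses$handedness[
    match(cohort$records$fetus_id, cohort$fetuses$fetus_id)]
}

#' Read a movement cohort from CSV
#'
#' Expects one movement per row with columns `fetus_id`, `handedness`, `gw`,
#' `target`, `hand`, `mt_ms` (or `mt_s`, converted to milliseconds on read)
#' and `tpv_pct`. Handedness must be constant within a fetus. Invalid rows
#' are reported with their row numbers.
#'
#' @param path path to a CSV file.
#' @return An `fh_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fetus_id", "handedness", "gw", "target", "hand", "tpv_pct")
  missing_cols <- setdiff(need, names(df))
  has_ms <- "mt_ms" %in% names(df)
  has_s <- "mt_s" %in% names(df)
  if (!has_ms && !has_s) missing_cols <- c(missing_cols, "mt_ms (or mt_s)")
  if (length(missing_cols)) {
    stopf("format error: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stopf("empty cohort: %s has no data rows", path)
  mt <- if (has_ms) as.numeric(df$mt_ms) else 1000 * as.numeric(df$mt_s)

  # roster from the per-row handedness labels; inconsistencies are errors
  lab <- tapply(df$handedness, df$fetus_id, function(h) unique(h))
  n_lab <- vapply(lab, length, integer(1))
  if (any(n_lab > 1L)) {
    stopf("inconsistent handedness for fetus %s",
          paste(names(lab)[n_lab > 1L], collapse = ", "))
  }
  fetuses <- data.frame(fetus_id = names(lab),
                        handedness = unlist(lab),
                        stringsAsFactors = FALSE)
  records <- data.frame(fetus_id = df$fetus_id, gw = df$gw,
                        target = df$target, hand = df$hand,
                        mt = mt, tpv = df$tpv_pct,
                        stringsAsFactors = FALSE)
  cohort(fetuses, records)
}

#' Write a movement cohort to CSV
#'
#' Inverse of [read_cohort()]: writes one movement per row with columns
#' `fetus_id,handedness,gw,target,hand,mt_ms,tpv_pct`. MT is written in
#' milliseconds at full double precision, so a read/write round trip
#' reproduces the cohort.
#'
#' @param cohort an `fh_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  check_cohort(cohort)
  out <- data.frame(
    fetus_id = cohort$records$fetus_id,
    handedness = record_handedness(cohort),
    gw = cohort$records$gw,
    target = cohort$records$target,
    hand = cohort$records$hand,
    mt_ms = format(cohort$records$mt, digits = 15, trim = TRUE,
                   scientific = FALSE),
    tpv_pct = format(cohort$records$tpv, digits = 15, trim = TRUE,
                     scientific = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
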