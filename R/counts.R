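#' Movement counts by handedness group, gestational week and hand
#'
#' Tabulates the number of recorded movements in each
#' (handedness group) x (gestational week) x (moving hand) cell, the layout
#' in which such studies summarise their recordings.
#'
#' @param cohort an `fh_cohort`.
#' @return An `fh_counts` data.frame with columns `group`, `gw`, `hand`,
#'   `count` (12 rows), carrying the grand total as attribute `grand_total`.
#' @export
counts_table <- function(cohort) {
  check_cohort(cohort)
  grp <- factor(record_handedness(cohort), levels = HAND_LEVELS)
  gw <- factor(cohort$records$gw, levels = GW_LEVELS)
  hand <- factor(cohort$records$hand, levels = HAND_LEVELS)
  tab <- as.data.frame(table(group = grp, gw = gw, hand = hand),
                       responseName = "count", stringsAsFactors = FALSE)
  tab$gw <- as.integer(tab$gw)
  tab <- tab[order(tab$gw, tab$group, tab$hand), c("group", "gw", "hand", "count")]
  rownames(tab) <- NULL
  structure(tab, grand_total = sum(tab$count),
            class = c("fh_counts", "data.frame"))
}

#' Packaged movement-count fixture
#'
#' The published hand-by-week-by-group movement counts shipped with the
#' package (grand total 488 movements over 29 fetuses; the per-target
#' breakdown is not public and is not stored).
#'
#' @return An `fh_counts` data.frame (see [counts_table()]).
#' @export
published_counts <- function() {
  path <- system.file("extdata", "published_counts.csv", package = "fetalhand",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$gw <- as.integer(tab$gw)
  tab$count <- as.integer(tab$count)
  structure(tab, grand_total = sum(tab$count),
            class = c("fh_counts", "data.frame"))
}

#' Per-column totals of a counts table
#'
#' @param counts an `fh_counts` table.
#' @return data.frame with one row per (group, gw) column and its total
#'   (right-hand plus left-hand cells).
#' @export
counts_totals <- function(counts) {
  agg <- stats::aggregate(count ~ group + gw, data = as.data.frame(counts),
                          FUN = sum)
  agg[order(agg$gw, agg$group), ]
}

#' Group-level movement summaries
#'
#' Means of the recorded movement counts for each handedness group: per
#' condition (the 18 hand x target x week conditions) and per fetus, plus
#' the right-handed fraction of the cohort.
#'
#' @param counts an `fh_counts` table (e.g. [published_counts()]).
#' @param n_right,n_left number of right-/left-handed fetuses (> 0).
#' @return data.frame with one row per group: `n_fetuses`, `total`,
#'   `mean_per_condition` (total / 18), `mean_per_fetus` (total / group
#'   size); attribute `prop_right` = n_right / (n_right + n_left).
#' @export
group_movement_summary <- function(counts, n_right, n_left) {
  if (n_right <= 0 || n_left <= 0) stopf("group sizes must be > 0")
  cdf <- as.data.frame(counts)
  tot <- vapply(HAND_LEVELS,
                function(g) sum(cdf$count[cdf$group == g]), numeric(1))
  n <- c(right = n_right, left = n_left)
  out <- data.frame(
    group = HAND_LEVELS,
    n_fetuses = as.integer(n),
    total = tot,
    mean_per_condition = tot / 18,
    mean_per_fetus = tot / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(out, prop_right = n_right / (n_right + n_left))
}
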