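#' Calibrated 2-D movement trajectory
#'
#' Container for a manually tracked wrist trajectory sampled at the
#' ultrasound frame rate (nominally 4 Hz). Positions are expressed in
#' intraocular-distance units after [calibrate()], which makes measurements
#' comparable across fetuses of different ages.
#'
#' @param times sample times in seconds, strictly increasing, length >= 3.
#' @param positions numeric matrix (n x 2) of coordinates.
#' @param calibration_length the calibration segment length in the raw
#'   units, > 0 (1 once calibrated).
#' @return An object of class `fh_trajectory`.
#' @export
trajectory <- function(times, positions, calibration_length = 1) {
  positions <- as.matrix(positions)
  if (length(times) < 3L) stopf("a trajectory needs at least 3 samples")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  if (nrow(positions) != length(times) || ncol(positions) != 2L) {
    stopf("positions must be a %d x 2 matrix", length(times))
  }
  if (!is.finite(calibration_length) || calibration_length <= 0) {
    stopf("calibration_length must be > 0")
  }
  structure(list(times = as.numeric(times),
                 positions = unname(positions),
                 calibration_length = calibration_length),
            class = "fh_trajectory")
}

#' Calibrate raw pixel coordinates to intraocular-distance units
#'
#' Divides raw tracked coordinates by the length (in pixels) of the
#' intraocular calibration segment measured on the same frames.
#'
#' @param raw_positions numeric matrix (n x 2) of pixel coordinates.
#' @param times sample times in seconds.
#' @param calibration_px intraocular segment length in pixels, > 0.
#' @return An `fh_trajectory` with positions in intraocular units.
#' @export
calibrate <- function(raw_positions, times, calibration_px) {
  if (!is.finite(calibration_px) || calibration_px <= 0) {
    stopf("calibration_px must be > 0")
  }
  trajectory(times, as.matrix(raw_positions) / calibration_px,
             calibration_length = 1)
}

#' Per-sample speed profile of a trajectory
#'
#' Speeds are derivatives of the tracked positions: central finite
#' differences on interior samples (second-order accurate, which matters at
#' the coarse 4 Hz sampling), one-sided differences at the two ends. No
#' smoothing is applied unless requested.
#'
#' @param traj an `fh_trajectory`.
#' @param smooth if `TRUE`, apply a 3-point moving average to the speeds.
#' @return Numeric vector of speeds (position units per second), one per
#'   sample.
#' @export
speed_profile <- function(traj, smooth = FALSE) {
  stopifnot(inherits(traj, "fh_trajectory"))
  t <- traj$times
  p <- traj$positions
  n <- length(t)
  vx <- numeric(n)
  vy <- numeric(n)
  i <- 2:(n - 1)
  vx[i] <- (p[i + 1, 1] - p[i - 1, 1]) / (t[i + 1] - t[i - 1])
  vy[i] <- (p[i + 1, 2] - p[i - 1, 2]) / (t[i + 1] - t[i - 1])
  vx[1] <- (p[2, 1] - p[1, 1]) / (t[2] - t[1])
  vy[1] <- (p[2, 2] - p[1, 2]) / (t[2] - t[1])
  vx[n] <- (p[n, 1] - p[n - 1, 1]) / (t[n] - t[n - 1])
  vy[n] <- (p[n, 2] - p[n - 1, 2]) / (t[n] - t[n - 1])
  speed <- sqrt(vx^2 + vy^2)
  if (smooth) {
    sm <- stats::filter(speed, rep(1 / 3, 3), sides = 2)
    speed[2:(n - 1)] <- sm[2:(n - 1)]
  }
  speed
}

#' Detect movement onset and offset from a speed profile
#'
#' The published record does not state an onset/offset rule, so the package
#' uses the standard kinematics convention: onset is the first sample where
#' speed rises above a fraction of peak speed (default 5%); offset is the
#' first later sample where speed falls below that threshold and stays
#' below it for at least 2 consecutive samples.
#'
#' @param speed numeric speed series with a positive peak.
#' @param threshold_frac threshold as a fraction of peak speed, in \[0, 1).
#' @return Integer vector `c(onset, offset)` (1-based sample indices).
#' @export
detect_bounds <- function(speed, threshold_frac = 0.05) {
  n <- length(speed)
  if (n == 0L || max(speed) <= 0) stopf("speed series has no positive peak")
  if (threshold_frac < 0 || threshold_frac >= 1) {
    stopf("threshold_frac must be in [0, 1)")
  }
  thr <- threshold_frac * max(speed)
  if (thr == 0) {
    # degenerate threshold: the whole series counts as the movement
    return(c(onset = 1L, offset = n))
  }
  above <- speed > thr
  onset <- which(above)[1]
  if (is.na(onset)) stopf("no onset crossing found")
  below <- !above
  for (j in seq(onset + 1L, length.out = max(0L, n - onset))) {
    if (below[j] && j < n && below[j + 1L]) {
      return(c(onset = onset, offset = j))
    }
  }
  stopf("no offset crossing found (speed never stays below threshold)")
}

#' Movement time and time-to-peak-velocity of a bounded movement
#'
#' MT is the duration from onset to offset in milliseconds. TPV is the time
#' at which speed peaks (deceleration begins), expressed as a percentage of
#' MT. The peak is searched over samples strictly after the onset up to and
#' including the offset, so TPV always lies in (0, 100].
#'
#' @param traj an `fh_trajectory`.
#' @param onset_index,offset_index sample indices bounding the movement,
#'   `onset_index < offset_index` (e.g. from [detect_bounds()]).
#' @param smooth passed to [speed_profile()].
#' @return Named list with `mt` (ms) and `tpv` (percent of MT).
#' @export
extract_metrics <- function(traj, onset_index, offset_index, smooth = FALSE) {
  stopifnot(inherits(traj, "fh_trajectory"))
  n <- length(traj$times)
  if (onset_index >= offset_index) stopf("onset must precede offset")
  if (onset_index < 1L || offset_index > n) stopf("indices out of range")
  speed <- speed_profile(traj, smooth = smooth)
  seg <- (onset_index + 1L):offset_index
  peak_index <- seg[which.max(speed[seg])]
  t_on <- traj$times[onset_index]
  t_off <- traj$times[offset_index]
  list(mt = 1000 * (t_off - t_on),
       tpv = 100 * (traj$times[peak_index] - t_on) / (t_off - t_on))
}

#' One-call MT/TPV extraction with automatic bounds
#'
#' @param traj an `fh_trajectory`.
#' @param threshold_frac passed to [detect_bounds()].
#' @param smooth passed to [speed_profile()].
#' @return As [extract_metrics()], plus `onset` and `offset` indices.
#' @export
trajectory_metrics <- function(traj, threshold_frac = 0.05, smooth = FALSE) {
  speed <- speed_profile(traj, smooth = smooth)
  b <- detect_bounds(speed, threshold_frac)
  m <- extract_metrics(traj, b[["onset"]], b[["offset"]], smooth = smooth)
  c(m, list(onset = b[["onset"]], offset = b[["offset"]]))
}
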