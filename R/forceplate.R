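# Force-plate reduction: raw 8-channel records -> net GRF + centre of
# pressure, and force-defined gait events.

#' Force-plate geometry
#'
#' Describes a four-sensor piezoelectric force plate.  The four load
#' cells sit at the corners of a rectangle, at `(+/-a, +/-b)` from the
#' plate centre, a distance `az0` below the top surface.  Sensor
#' numbering follows the usual convention for paired shear channels:
#' sensor 1 at `(-a, +b)`, 2 at `(+a, +b)`, 3 at `(+a, -b)`,
#' 4 at `(-a, -b)`, so that channels `fx12`/`fx34` pair sensors sharing
#' a `y` row and `fy14`/`fy23` pair sensors sharing an `x` column.
#'
#' @param a Sensor offset from the plate centre along lateral X (m), > 0.
#' @param b Sensor offset along anterior Y (m), > 0.
#' @param az0 Depth of the sensor plane below the top surface (m), >= 0.
#'   Shear forces acting at the surface produce moments about the sensor
#'   plane; `az0` corrects the centre-of-pressure estimate for them.
#' @param origin_offset 3-vector (m) from the global origin to the plate
#'   centre at the top surface.  The default `c(0, 0, 0)` puts the
#'   global origin at the plate centre; a corner-origin convention is
#'   expressed by a non-zero offset.
#' @param force_rate Sampling rate of the force channels (Hz).
#' @return An object of class `plate_geometry`.
#' @export
plate_geometry <- function(a = 0.12, b = 0.20, az0 = 0.01,
                           origin_offset = c(0, 0, 0),
                           force_rate = 3000) {
  if (!(a > 0 && b > 0 && az0 >= 0 && force_rate > 0))
    hs_stop("require a > 0, b > 0, az0 >= 0, force_rate > 0",
            "heelstrike_input_error", stage = "forceplate")
  if (length(origin_offset) != 3L)
    hs_stop("origin_offset must be a 3-vector",
            "heelstrike_input_error", stage = "forceplate")
  structure(list(a = a, b = b, az0 = az0,
                 origin_offset = as.numeric(origin_offset),
                 force_rate = force_rate),
            class = "plate_geometry")
}

channel_names <- c("fx12", "fx34", "fy14", "fy23",
                   "fz1", "fz2", "fz3", "fz4")

#' Raw force-plate channel record
#'
#' @param time Strictly increasing sample times (s).
#' @param channels Data frame or named list with the eight channels
#'   `fx12, fx34, fy14, fy23, fz1, fz2, fz3, fz4` (N), each the same
#'   length as `time`.  Channels are assumed to be in reaction
#'   convention (force exerted by the plate on the foot).
#' @return An object of class `channel_record` (a data frame).
#' @export
channel_record <- function(time, channels) {
  check_time(time, "forceplate")
  miss <- setdiff(channel_names, names(channels))
  if (length(miss))
    hs_stop(paste("missing channels:", paste(miss, collapse = ", ")),
            "heelstrike_input_error", stage = "forceplate")
  n <- length(time)
  for (ch in channel_names)
    if (length(channels[[ch]]) != n)
      hs_stop(sprintf("channel '%s' length %d != time length %d",
                      ch, length(channels[[ch]]), n),
              "heelstrike_input_error", stage = "forceplate")
  out <- data.frame(time = time)
  for (ch in channel_names) out[[ch]] <- as.numeric(channels[[ch]])
  class(out) <- c("channel_record", "data.frame")
  out
}

# Sensor x/y coordinates in plate frame, in channel order fz1..fz4.
sensor_xy <- function(geom) {
  cbind(x = c(-geom$a, geom$a, geom$a, -geom$a),
        y = c(geom$b, geom$b, -geom$b, -geom$b))
}

#' Reduce raw channels to net GRF and centre of pressure
#'
#' Net force: `F_X = fx12 + fx34`, `F_Y = fy14 + fy23`,
#' `F_Z = fz1 + fz2 + fz3 + fz4`.  Plate-frame COP from the vertical
#' sensor moments with the shear correction for sensor depth:
#' `x_cop = (sum(x_i fz_i) + az0 F_X) / F_Z` (and likewise for y),
#' then shifted by the plate origin offset into the global frame.
#' COP is ill-conditioned as `F_Z -> 0`, so samples with
#' `F_Z < cop_force_threshold` are marked invalid and their COP set to
#' `NA`.
#'
#' @param rec A [channel_record()].
#' @param geom A [plate_geometry()].
#' @param cop_force_threshold Minimum vertical force (N) for a valid
#'   COP sample.
#' @return An object of class `grf_series`: a data frame with columns
#'   `time, F_X, F_Y, F_Z, cop_X, cop_Y, cop_valid`.
#' @export
reduce_channels <- function(rec, geom, cop_force_threshold = 10) {
  stopifnot(inherits(rec, "channel_record"), inherits(geom, "plate_geometry"))
  F_X <- rec$fx12 + rec$fx34
  F_Y <- rec$fy14 + rec$fy23
  F_Z <- rec$fz1 + rec$fz2 + rec$fz3 + rec$fz4
  s <- sensor_xy(geom)
  mx <- rec$fz1 * s[1, "x"] + rec$fz2 * s[2, "x"] +
        rec$fz3 * s[3, "x"] + rec$fz4 * s[4, "x"]
  my <- rec$fz1 * s[1, "y"] + rec$fz2 * s[2, "y"] +
        rec$fz3 * s[3, "y"] + rec$fz4 * s[4, "y"]
  ok <- F_Z >= cop_force_threshold
  cop_X <- cop_Y <- rep(NA_real_, length(F_Z))
  cop_X[ok] <- (mx[ok] + geom$az0 * F_X[ok]) / F_Z[ok] + geom$origin_offset[1]
  cop_Y[ok] <- (my[ok] + geom$az0 * F_Y[ok]) / F_Z[ok] + geom$origin_offset[2]
  grf_series(rec$time, F_X, F_Y, F_Z, cop_X, cop_Y, ok)
}

#' Ground-reaction-force series
#'
#' @param time Sample times (s).
#' @param F_X,F_Y,F_Z Force on the foot (N); X lateral, Y anterior,
#'   Z vertical up.
#' @param cop_X,cop_Y Centre of pressure at the plate surface, global
#'   frame (m); `NA` where invalid.
#' @param cop_valid Logical validity mask for the COP.
#' @return An object of class `grf_series` (a data frame).
#' @export
grf_series <- function(time, F_X, F_Y, F_Z, cop_X, cop_Y,
                       cop_valid = is.finite(cop_X) & is.finite(cop_Y)) {
  check_time(time, "forceplate")
  n <- length(time)
  if (!all(lengths(list(F_X, F_Y, F_Z, cop_X, cop_Y, cop_valid)) == n))
    hs_stop("all GRF columns must match the time length",
            "heelstrike_input_error", stage = "forceplate")
  out <- data.frame(time = time, F_X = F_X, F_Y = F_Y, F_Z = F_Z,
                    cop_X = cop_X, cop_Y = cop_Y, cop_valid = cop_valid)
  class(out) <- c("grf_series", "data.frame")
  out
}

#' Detect contact onset from the vertical GRF
#'
#' Contact onset `t0` is defined as the instant at which the GRF leaves
#' zero.  On sampled, possibly noisy data this is located as the last
#' sample at or below `floor_threshold` preceding the first sample
#' above `rise_threshold`.
#'
#' @param grf A [grf_series()].
#' @param rise_threshold Force level (N) that must be exceeded for
#'   contact to be declared.
#' @param floor_threshold Quiescent-baseline level (N).
#' @return Contact-onset time `t0` (s).
#' @export
detect_contact_onset <- function(grf, rise_threshold = 10,
                                 floor_threshold = 2) {
  stopifnot(inherits(grf, "grf_series"))
  i_rise <- which(grf$F_Z > rise_threshold)[1]
  if (is.na(i_rise))
    hs_stop(sprintf("vertical force never exceeds %g N: no contact",
                    rise_threshold),
            "heelstrike_nocontact_error", stage = "forceplate")
  below <- which(grf$F_Z[seq_len(i_rise - 1L)] <= floor_threshold)
  if (!length(below))
    hs_stop("no quiescent baseline before the force rise",
            "heelstrike_nocontact_error", stage = "forceplate")
  grf$time[max(below)]
}

# Prominence of local maxima within a window: height above the higher
# of the two bounding minima (taken to the nearest higher sample or the
# window edge on each side).
local_peaks <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

peak_prominence <- function(y, i) {
  n <- length(y)
  left <- y[seq_len(i - 1L)]
  hi_l <- which(left > y[i])
  lo_l <- min(y[(if (length(hi_l)) max(hi_l) else 1L):(i - 1L)])
  right <- y[(i + 1L):n]
  hi_r <- which(right > y[i])
  lo_r <- min(y[(i + 1L):(if (length(hi_r)) i + min(hi_r) else n)])
  y[i] - max(lo_l, lo_r)
}

#' Detect the impact-transient force peak
#'
#' Finds the first sufficiently prominent local maximum of the vertical
#' GRF in the interval `(t0, t0 + search_window]` -- the impact
#' transient that precedes the main stance peaks.  If no local maximum
#' reaches the required prominence the argmax over the window is used.
#'
#' @param grf A [grf_series()].
#' @param t0 Contact-onset time (s).
#' @param search_window Window length after `t0` (s).
#' @param min_prominence_fraction Required prominence as a fraction of
#'   the window's maximum vertical force.
#' @return Impact-peak time `t_p` (s).
#' @export
detect_impact_peak <- function(grf, t0, search_window = 0.060,
                               min_prominence_fraction = 0.05) {
  stopifnot(inherits(grf, "grf_series"))
  idx <- which(grf$time > t0 & grf$time <= t0 + search_window)
  if (length(idx) < 3L)
    hs_stop("empty or too-short search window after t0",
            "heelstrike_input_error", stage = "forceplate")
  y <- grf$F_Z[idx]
  need <- min_prominence_fraction * max(y)
  for (i in local_peaks(y)) {
    if (peak_prominence(y, i) >= need) return(grf$time[idx[i]])
  }
  grf$time[idx[which.max(y)]]
}
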