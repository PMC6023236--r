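# Marker kinematics: local lower-leg frame from a two-LED cluster,
# heel-point estimation, heel trajectory, deformation and its events.

#' Marker series from a two-LED lower-leg cluster
#'
#' @param time Sample times (s), kinematic rate.
#' @param led1 n-by-3 matrix of global positions (m) of the lower
#'   marker (local frame origin).
#' @param led2 n-by-3 matrix for the upper marker.
#' @param distance_warn_tol Warn when the inter-marker distance varies
#'   more than this over the trial (m); rigid-cluster check.
#' @return An object of class `marker_series`.
#' @export
marker_series <- function(time, led1, led2, distance_warn_tol = 1e-3) {
  check_time(time, "kinematics")
  led1 <- as.matrix(led1); led2 <- as.matrix(led2)
  if (!all(dim(led1) == c(length(time), 3L)) ||
      !all(dim(led2) == c(length(time), 3L)))
    hs_stop("led1/led2 must be n-by-3 with n = length(time)",
            "heelstrike_input_error", stage = "kinematics")
  d <- sqrt(rowSums((led2 - led1)^2))
  if (diff(range(d)) > distance_warn_tol)
    hs_warn(sprintf(
      "inter-marker distance varies by %.2f mm over the trial (> %.1f mm): cluster may not be rigid",
      1000 * diff(range(d)), 1000 * distance_warn_tol),
      "heelstrike_rigidity_warning")
  structure(list(time = time, led1 = unname(led1), led2 = unname(led2)),
            class = "marker_series")
}

#' Inter-marker distance of a marker series
#' @param markers A [marker_series()].
#' @return Vector of per-sample distances (m).
#' @export
marker_distance <- function(markers) {
  sqrt(rowSums((markers$led2 - markers$led1)^2))
}

#' Filter a marker series coordinate-wise
#'
#' Applies [zero_phase_lowpass()] to each of the six marker
#' coordinates.
#'
#' @param markers A [marker_series()].
#' @param cutoff,order Passed to [zero_phase_lowpass()].
#' @return A filtered `marker_series`.
#' @export
filter_markers <- function(markers, cutoff = 100, order = 2) {
  rate <- 1 / stats::median(diff(markers$time))
  f <- function(m) apply(m, 2, zero_phase_lowpass,
                         cutoff = cutoff, rate = rate, order = order)
  out <- markers
  out$led1 <- f(markers$led1)
  out$led2 <- f(markers$led2)
  out
}

#' Build the local lower-leg frame at every sample
#'
#' The local frame has its origin at the lower marker.  Local z is the
#' unit vector from led1 to led2; local y is the unit vector orthogonal
#' to z with zero global-X component (it lies in the plane of
#' progression, a plane parallel to the global YZ plane) and positive
#' global-Y (anterior) component; local x completes the right-handed
#' frame (x = y cross z).
#'
#' @param markers A [marker_series()] (normally filtered).
#' @param y_sign `+1` (default) for an anterior-positive local y, `-1`
#'   to flip it (the progression plane fixes y only up to sign).
#' @return An object of class `frame_series`: list with `time`, a
#'   3-by-3-by-n `rotation` array (columns = local x, y, z expressed in
#'   global coordinates), and an n-by-3 `origin` (led1).
#' @export
build_local_frames <- function(markers, y_sign = 1) {
  stopifnot(inherits(markers, "marker_series"))
  d <- markers$led2 - markers$led1
  nrm <- sqrt(rowSums(d^2))
  bad <- which(nrm < 1e-9)
  if (length(bad))
    hs_stop(sprintf("coincident markers at sample %d", bad[1]),
            "heelstrike_geometry_error", stage = "kinematics")
  z <- d / nrm
  pl <- sqrt(z[, 2]^2 + z[, 3]^2)   # projection of z onto the YZ plane
  bad <- which(pl < 1e-9)
  if (length(bad))
    hs_stop(sprintf("local z parallel to global X at sample %d: local y undefined",
                    bad[1]),
            "heelstrike_geometry_error", stage = "kinematics")
  # y orthogonal to z with zero global-X component; anterior-positive
  # by default.
  sgn <- sign(y_sign) * ifelse(z[, 3] < 0, -1, 1)
  y <- cbind(0, sgn * z[, 3] / pl, -sgn * z[, 2] / pl)
  x <- cbind(y[, 2] * z[, 3] - y[, 3] * z[, 2],
             y[, 3] * z[, 1] - y[, 1] * z[, 3],
             y[, 1] * z[, 2] - y[, 2] * z[, 1])
  n <- length(markers$time)
  rot <- array(0, dim = c(3, 3, n))
  rot[, 1, ] <- t(x); rot[, 2, ] <- t(y); rot[, 3, ] <- t(z)
  structure(list(time = markers$time, rotation = rot,
                 origin = markers$led1),
            class = "frame_series")
}

#' Transform the centre of pressure into the local frame
#'
#' Valid COP samples (at the force rate) are linearly interpolated onto
#' the kinematic timestamps that fall inside the valid-COP time range,
#' and each interpolated global COP point -- placed at the plate
#' surface height -- is expressed in the local frame of that sample:
#' `r = R^T (COP_global - L)`.
#'
#' @param frames A [build_local_frames()] result.
#' @param grf A [grf_series()] with valid COP samples.
#' @param surface_z Global Z of the plate surface (m).
#' @return Data frame of class `local_cop` with columns
#'   `time, x, y, z`.
#' @export
localize_cop <- function(frames, grf, surface_z = 0) {
  stopifnot(inherits(frames, "frame_series"), inherits(grf, "grf_series"))
  v <- which(grf$cop_valid)
  if (length(v) < 2L)
    hs_stop("fewer than two valid COP samples",
            "heelstrike_input_error", stage = "kinematics")
  t_lo <- grf$time[v[1]]; t_hi <- grf$time[v[length(v)]]
  ki <- which(frames$time >= t_lo & frames$time <= t_hi)
  if (!length(ki))
    hs_stop("COP time range not covered by the kinematic frames",
            "heelstrike_sync_error", stage = "kinematics")
  tk <- frames$time[ki]
  cx <- stats::approx(grf$time[v], grf$cop_X[v], xout = tk)$y
  cy <- stats::approx(grf$time[v], grf$cop_Y[v], xout = tk)$y
  out <- matrix(0, length(ki), 3)
  for (j in seq_along(ki)) {
    i <- ki[j]
    p <- c(cx[j], cy[j], surface_z) - frames$origin[i, ]
    out[j, ] <- crossprod(frames$rotation[, , i], p)
  }
  res <- data.frame(time = tk, x = out[, 1], y = out[, 2], z = out[, 3])
  class(res) <- c("local_cop", "data.frame")
  res
}

# Geometric median by Weiszfeld iteration (config alternative to the
# marginal median).
geometric_median <- function(m, tol = 1e-10, maxit = 200L) {
  p <- colMeans(m)
  for (i in seq_len(maxit)) {
    d <- sqrt(rowSums(sweep(m, 2, p)^2))
    d[d < 1e-12] <- 1e-12
    p2 <- colSums(m / d) / sum(1 / d)
    if (sqrt(sum((p2 - p)^2)) < tol) return(p2)
    p <- p2
  }
  p
}

#' Estimate the bone-fixed heel point
#'
#' The heel point is taken as the median local-frame position of the
#' COP samples surrounding the impact peak: the window starts at the
#' first force sample whose vertical GRF reaches 25% of the impact-peak
#' force and ends so that the peak sample is the window midpoint.  The
#' median makes the estimate robust to isolated COP outliers.
#'
#' @param local_cop A [localize_cop()] result.
#' @param grf A [grf_series()].
#' @param t_p Impact-peak time (s).
#' @param median_kind `"marginal"` (component-wise, default) or
#'   `"geometric"`.
#' @return Numeric 3-vector `r_H` (m), the constant local heel-point
#'   position; the force-base window is attached as attribute
#'   `"window"`.
#' @export
estimate_heel_point <- function(local_cop, grf, t_p,
                                median_kind = c("marginal", "geometric")) {
  median_kind <- match.arg(median_kind)
  stopifnot(inherits(local_cop, "local_cop"), inherits(grf, "grf_series"))
  p <- which.min(abs(grf$time - t_p))
  s <- which(grf$F_Z >= 0.25 * grf$F_Z[p])[1]
  if (is.na(s) || s > p)
    hs_stop("no force sample reaches 25% of the impact peak before the peak",
            "heelstrike_insufficient_data_error", stage = "kinematics")
  e <- min(2L * p - s, nrow(grf))
  inwin <- which(local_cop$time >= grf$time[s] &
                   local_cop$time <= grf$time[e])
  if (length(inwin) < 3L) {
    # The symmetric 25%-of-peak window presumes an interior impact
    # peak; a heavily damped contact peaks at touchdown and collapses
    # the window.  Widen forward to the first few COP samples instead.
    cand <- which(local_cop$time >= grf$time[s])
    if (length(cand) < 3L)
      hs_stop("fewer than 3 local COP samples at or after the heel-point window",
              "heelstrike_insufficient_data_error", stage = "kinematics")
    inwin <- cand[seq_len(min(5L, length(cand)))]
    hs_warn(sprintf(
      "heel-point window degenerate (impact peak %.1f ms after its 25%% threshold); widened forward to %d COP samples",
      1000 * (grf$time[p] - grf$time[s]), length(inwin)),
      "heelstrike_window_warning")
  }
  m <- as.matrix(local_cop[inwin, c("x", "y", "z")])
  r_H <- if (median_kind == "marginal") apply(m, 2, stats::median)
         else geometric_median(m)
  names(r_H) <- c("x", "y", "z")
  attr(r_H, "window") <- c(start = grf$time[s],
                           end = max(grf$time[e],
                                     local_cop$time[inwin[length(inwin)]]))
  r_H
}

#' Reconstruct the global heel trajectory and deformation
#'
#' Maps the constant local heel point through the time-variant frame:
#' `R_H(t) = L(t) + R(t) r_H`.  Foot-ankle deformation is the heel
#' displacement since contact, `S(t) = R_H(t) - R_H(t0)` (with
#' `R_H(t0)` linearly interpolated to `t0`), and the vertical heel
#' velocity is the central-difference gradient of the vertical heel
#' position on the kinematic time base.
#'
#' @param frames A [build_local_frames()] result (filtered markers).
#' @param r_H Local heel point, 3-vector (m).
#' @param t0 Contact-onset time (s); must lie inside the kinematic
#'   time range.
#' @return An object of class `heel_track`: list with `time`, `r_H`,
#'   n-by-3 `R_H` and `S`, and `Zdot_H`.
#' @export
reconstruct_heel_track <- function(frames, r_H, t0) {
  stopifnot(inherits(frames, "frame_series"))
  tt <- frames$time
  if (t0 < tt[1] || t0 > tt[length(tt)])
    hs_stop("t0 outside the kinematic time range",
            "heelstrike_sync_error", stage = "kinematics")
  n <- length(tt)
  R_H <- frames$origin +
    t(apply(frames$rotation, 3, function(R) R %*% r_H))
  R0 <- vapply(1:3, function(k) interp1(tt, R_H[, k], t0, "kinematics"),
               numeric(1))
  S <- sweep(R_H, 2, R0)
  structure(list(time = tt, r_H = r_H, R_H = R_H, S = S,
                 Zdot_H = grad1(R_H[, 3], tt), t0 = t0),
            class = "heel_track")
}

#' Detect the end of heel strike (zero vertical heel velocity)
#'
#' Heel strike ends at the first upward zero crossing of the vertical
#' heel velocity after contact -- the instant of maximal vertical
#' foot-ankle compression.  The crossing is located with sub-sample
#' resolution by linear interpolation between the bracketing kinematic
#' samples.
#'
#' @param track A [reconstruct_heel_track()] result.
#' @param t0 Contact-onset time (s).
#' @param max_lag Longest admissible interval after `t0` (s).
#' @return End-of-heel-strike time `t_e` (s).
#' @export
detect_deformation_end <- function(track, t0, max_lag = 0.100) {
  stopifnot(inherits(track, "heel_track"))
  v0 <- interp1(track$time, track$Zdot_H, t0, "kinematics")
  if (v0 >= 0)
    hs_stop("vertical heel velocity at t0 is not negative: heel not descending",
            "heelstrike_event_error", stage = "kinematics")
  idx <- which(track$time > t0 & track$time <= t0 + max_lag)
  v <- c(v0, track$Zdot_H[idx])
  tt <- c(t0, track$time[idx])
  cross <- which(v[-length(v)] < 0 & v[-1] >= 0)[1]
  if (is.na(cross))
    hs_stop(sprintf("no upward zero crossing of the heel velocity within %g ms of t0",
                    1000 * max_lag),
            "heelstrike_event_error", stage = "kinematics")
  i <- cross
  tt[i] + (0 - v[i]) * (tt[i + 1] - tt[i]) / (v[i + 1] - v[i])
}
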