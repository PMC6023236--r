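# The central fitting function: one trial in, one classed fit out.

#' Estimate heel-strike energy absorption for one trial
#'
#' Runs the full per-trial pipeline on synchronized force-plate and
#' marker data: channel reduction to net GRF and COP, contact-onset and
#' impact-peak detection, zero-phase marker filtering, local-frame
#' construction, heel-point estimation, heel-trajectory and deformation
#' reconstruction, detection of the end of heel strike (zero vertical
#' heel velocity), the force-integral work, and the effective-mass
#' model quantities.
#'
#' @param force A force file path (see [read_force_csv()]), a
#'   [channel_record()], or a pre-reduced [grf_series()].
#' @param markers A marker file path (see [read_marker_csv()]) or a
#'   [marker_series()].
#' @param body_mass Participant body mass (kg), used only to express
#'   the effective masses as a percentage of body mass; may be `NULL`.
#' @param config A [pipeline_config()].
#' @param heel_point_offset Local-frame 3-vector (m) added to the
#'   estimated heel point before reconstruction; `c(0, 0, 0)` for the
#'   default heel point, non-zero for sensitivity analyses.
#' @return An object of class `heel_strike` with components
#'   `energetics` (named list of all scalar results), `events`
#'   (`t0`, `t_p`, `t_e`), `grf`, `track`, `local_cop`, `r_H`,
#'   `flags`, `config`, and `log`.  Methods: [print.heel_strike()],
#'   [summary.heel_strike()], [coef.heel_strike()],
#'   [plot.heel_strike()].
#' @export
heel_strike <- function(force, markers, body_mass = NULL,
                        config = pipeline_config(),
                        heel_point_offset = c(0, 0, 0)) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  flags <- character(0)

  # --- force side -----------------------------------------------------
  if (is.character(force)) force <- read_force_csv(force)
  geom <- do.call(plate_geometry, config$plate)
  grf <- if (inherits(force, "channel_record")) {
    reduce_channels(force, geom, config$events$cop_force_threshold)
  } else if (inherits(force, "grf_series")) force else
    hs_stop("force must be a path, channel_record or grf_series",
            "heelstrike_input_error", stage = "forceplate")
  if (isTRUE(config$energetics$filter_force)) {
    rate <- 1 / stats::median(diff(grf$time))
    for (k in c("F_X", "F_Y", "F_Z"))
      grf[[k]] <- zero_phase_lowpass(grf[[k]], config$kinematics$cutoff_hz,
                                     rate, config$kinematics$filter_order)
  }
  t0 <- detect_contact_onset(grf, config$events$rise_threshold,
                             config$events$floor_threshold)
  t_p <- detect_impact_peak(grf, t0, config$events$peak_window,
                            config$events$min_prominence_fraction)
  log$events_force <- list(t0 = t0, t_p = t_p)

  # --- kinematic side -------------------------------------------------
  if (is.character(markers)) markers <- read_marker_csv(markers)
  stopifnot(inherits(markers, "marker_series"))
  raw_led1 <- markers$led1
  markers_f <- filter_markers(markers, config$kinematics$cutoff_hz,
                              config$kinematics$filter_order)
  frames <- build_local_frames(markers_f, config$kinematics$y_sign)
  lcop <- localize_cop(frames, grf, config$kinematics$surface_z)
  r_H <- estimate_heel_point(lcop, grf, t_p, config$kinematics$median_kind)
  r_used <- r_H + heel_point_offset
  track <- reconstruct_heel_track(frames, r_used, t0)
  t_e <- detect_deformation_end(track, t0)
  kin_dt <- stats::median(diff(markers$time))
  if (t_p > t_e + kin_dt) {
    hs_warn(sprintf("impact peak (%.1f ms) after end of heel strike (%.1f ms)",
                    1000 * (t_p - t0), 1000 * (t_e - t0)),
            "heelstrike_event_warning")
    flags <- c(flags, "t_p_after_t_e")
  }
  log$heel_point <- list(r_H = unname(r_H), offset = heel_point_offset,
                         window = attr(r_H, "window"))

  # --- energetics -----------------------------------------------------
  g <- config$energetics$g
  W <- work_by_grf(grf, track, t0, t_e)
  Zdot_t0 <- interp1(track$time, track$Zdot_H, t0, "energetics")
  Zdot_tp <- interp1(track$time, track$Zdot_H, t_p, "energetics")
  z_at <- function(t) interp1(track$time, track$R_H[, 3], t, "energetics")
  S_te <- vapply(1:3, function(k)
    interp1(track$time, track$S[, k], t_e, "energetics"), numeric(1))

  em <- function(expr, what) {
    tryCatch(expr, heelstrike_model_error = function(e) {
      flags <<- c(flags, paste0(what, ": ", conditionMessage(e)))
      NA_real_
    })
  }
  M_e <- em(effective_mass(grf, Zdot_t0, 0, t0, t_e, g), "M_e")
  M_p <- em(effective_mass(grf, Zdot_t0, Zdot_tp, t0, t_p, g), "M_p")
  M_p_CS <- em(effective_mass(grf, Zdot_t0, 0, t0, t_p, g), "M_p_CS")
  dE_e <- if (is.na(M_e)) NA_real_ else
    effective_mass_energy(M_e, Zdot_t0, 0, z_at(t0), z_at(t_e), g)
  dE_p <- if (is.na(M_p)) NA_real_ else
    effective_mass_energy(M_p, Zdot_t0, Zdot_tp, z_at(t0), z_at(t_p), g)
  dE_p_CS <- if (is.na(M_p_CS)) NA_real_ else
    effective_mass_energy(M_p_CS, Zdot_t0, 0, z_at(t0), z_at(t_p), g)

  n <- length(markers_f$time)
  walking_speed <- (markers_f$led1[n, 2] - markers_f$led1[1, 2]) /
    (markers_f$time[n] - markers_f$time[1])

  pct <- function(M) if (is.null(body_mass)) NA_real_ else 100 * M / body_mass
  energetics <- list(
    W = W$W, W_X = W$W_X, W_Y = W$W_Y, W_Z = W$W_Z,
    dE_e = dE_e, dE_p = dE_p, dE_p_CS = dE_p_CS,
    M_e = M_e, M_p = M_p, M_p_CS = M_p_CS,
    M_e_pct = pct(M_e), M_p_pct = pct(M_p), M_p_CS_pct = pct(M_p_CS),
    S_te_X = S_te[1], S_te_Y = S_te[2], S_te_Z = S_te[3],
    S_te_mag = sqrt(sum(S_te^2)),
    Zdot_t0 = Zdot_t0, Zdot_tp = Zdot_tp,
    t_p_ms = 1000 * (t_p - t0), t_e_ms = 1000 * (t_e - t0),
    walking_speed = walking_speed,
    body_mass = if (is.null(body_mass)) NA_real_ else body_mass,
    g = g)

  structure(list(energetics = energetics,
                 events = list(t0 = t0, t_p = t_p, t_e = t_e),
                 grf = grf, track = track, local_cop = lcop,
                 r_H = r_used, raw_led1 = raw_led1,
                 flags = flags, config = config, log = log),
            class = "heel_strike")
}

#' @export
print.heel_strike <- function(x, ...) {
  e <- x$energetics
  cat("Heel-strike energy absorption (one trial)\n")
  cat(sprintf("  heel strike: t0 = %.4f s, t_p = t0 + %.1f ms, t_e = t0 + %.1f ms (t_e/t_p = %.2f)\n",
              x$events$t0, e$t_p_ms, e$t_e_ms, e$t_e_ms / e$t_p_ms))
  cat(sprintf("  deformation at t_e: S = (%.1f, %.1f, %.1f) mm, |S| = %.1f mm\n",
              1000 * e$S_te_X, 1000 * e$S_te_Y, 1000 * e$S_te_Z,
              1000 * e$S_te_mag))
  cat(sprintf("  force-integral work:  W = %.2f J  (X %.2f, Y %.2f, Z %.2f)\n",
              e$W, e$W_X, e$W_Y, e$W_Z))
  cat(sprintf("  effective-mass model: dE_e = %.2f J, dE_p = %.2f J, dE_p_CS = %.2f J\n",
              e$dE_e, e$dE_p, e$dE_p_CS))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.heel_strike <- function(object, ...) {
  e <- object$energetics
  c(W = e$W, W_X = e$W_X, W_Y = e$W_Y, W_Z = e$W_Z,
    dE_e = e$dE_e, dE_p = e$dE_p, dE_p_CS = e$dE_p_CS,
    M_e = e$M_e, M_p = e$M_p, M_p_CS = e$M_p_CS)
}

#' @export
summary.heel_strike <- function(object, ...) {
  structure(list(fit = object), class = "summary.heel_strike")
}

#' @export
print.summary.heel_strike <- function(x, ...) {
  f <- x$fit; e <- f$energetics
  print(f)
  cat(sprintf("  heel point r_H (local, m): (%.4f, %.4f, %.4f)\n",
              f$r_H[1], f$r_H[2], f$r_H[3]))
  cat(sprintf("  heel velocity: Zdot(t0) = %.3f m/s, Zdot(t_p) = %.3f m/s\n",
              e$Zdot_t0, e$Zdot_tp))
  cat(sprintf("  effective masses: M_e = %.2f kg, M_p = %.2f kg, M_p_CS = %.2f kg\n",
              e$M_e, e$M_p, e$M_p_CS))
  if (is.finite(e$M_e_pct))
    cat(sprintf("    as %% body mass (%.1f kg): %.1f%%, %.1f%%, %.1f%%\n",
                e$body_mass, e$M_e_pct, e$M_p_pct, e$M_p_CS_pct))
  cat(sprintf("  walking speed (anterior lower-LED drift): %.2f m/s\n",
              e$walking_speed))
  invisible(x)
}

#' Plot a heel-strike fit
#'
#' @param x A [heel_strike()] fit.
#' @param which Panels to draw: `"force"` (GRF components about heel
#'   strike), `"deformation"` (foot-ankle deformation components),
#'   `"cop"` (local COP cloud with the estimated heel point), and/or
#'   `"acceleration"` (vertical heel acceleration vs the vertical GRF).
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.heel_strike <- function(x, which = c("force", "deformation"), ...) {
  ev <- x$events
  span <- c(ev$t0 - 0.01, ev$t_e + 0.02)
  marks <- function() {
    graphics::abline(v = c(ev$t0, ev$t_p, ev$t_e), lty = 3)
    graphics::mtext(c("t0", "tp", "te"), side = 3,
                    at = c(ev$t0, ev$t_p, ev$t_e), cex = 0.7)
  }
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (w in which) {
    if (w == "force") {
      i <- x$grf$time >= span[1] & x$grf$time <= span[2]
      graphics::matplot(x$grf$time[i],
                        cbind(x$grf$F_X, x$grf$F_Y, x$grf$F_Z)[i, ],
                        type = "l", lty = 1, col = c(3, 4, 1),
                        xlab = "time (s)", ylab = "GRF (N)")
      graphics::legend("topleft", c("F_X", "F_Y", "F_Z"),
                       col = c(3, 4, 1), lty = 1, bty = "n")
      marks()
    } else if (w == "deformation") {
      i <- x$track$time >= span[1] & x$track$time <= span[2]
      graphics::matplot(x$track$time[i], 1000 * x$track$S[i, ],
                        type = "l", lty = 1, col = c(3, 4, 1),
                        xlab = "time (s)", ylab = "deformation (mm)")
      graphics::legend("bottomleft", c("S_X", "S_Y", "S_Z"),
                       col = c(3, 4, 1), lty = 1, bty = "n")
      marks()
    } else if (w == "cop") {
      graphics::plot(1000 * x$local_cop$y, 1000 * x$local_cop$z,
                     pch = 16, cex = 0.5, col = "grey40",
                     xlab = "local y (mm)", ylab = "local z (mm)",
                     asp = 1)
      graphics::points(1000 * x$r_H[2], 1000 * x$r_H[3], pch = 3,
                       col = 2, cex = 1.5)
      graphics::legend("topright", c("COP samples", "heel point"),
                       pch = c(16, 3), col = c("grey40", 2), bty = "n")
    } else if (w == "acceleration") {
      tr <- x$track
      acc <- grad1(tr$Zdot_H, tr$time)
      i <- tr$time >= span[1] & tr$time <= span[2]
      graphics::plot(tr$time[i], acc[i], type = "l",
                     xlab = "time (s)",
                     ylab = "vertical heel acceleration (m/s^2)")
      graphics::abline(h = -x$energetics$g, lty = 2)
      j <- x$grf$time >= span[1] & x$grf$time <= span[2]
      graphics::lines(x$grf$time[j],
                      x$grf$F_Z[j] / max(x$grf$F_Z[j]) * max(acc[i]),
                      col = "grey60")
      marks()
    }
  }
  invisible(x)
}

#' Sensitivity of the energetics to the heel-point location
#'
#' Re-runs the trial with the heel point displaced by a fixed
#' local-frame offset and reports the relative change of every scalar
#' result.  The default offset reproduces the classic probe point one
#' centimetre lateral (+x), posterior (-y) and inferior (-z) of the
#' estimated heel point.
#'
#' @inheritParams heel_strike
#' @param offset Local-frame displacement (m) of the probe point.
#' @return An object of class `heel_point_sensitivity`: list with the
#'   `baseline` and `shifted` fits and a data frame `deltas` of
#'   baseline value, shifted value, and relative change per variable.
#' @export
heel_point_sensitivity <- function(force, markers, body_mass = NULL,
                                   config = pipeline_config(),
                                   offset = c(0.01, -0.01, -0.01)) {
  if (is.character(force)) force <- read_force_csv(force)
  if (is.character(markers)) markers <- read_marker_csv(markers)
  base <- heel_strike(force, markers, body_mass, config)
  shift <- heel_strike(force, markers, body_mass, config,
                       heel_point_offset = offset)
  vars <- names(base$energetics)
  b <- unlist(base$energetics)[vars]
  s <- unlist(shift$energetics)[vars]
  rel <- ifelse(b == 0, ifelse(s == 0, 0, NA_real_), (s - b) / abs(b))
  structure(list(baseline = base, shifted = shift, offset = offset,
                 deltas = data.frame(variable = vars, baseline = unname(b),
                                     shifted = unname(s),
                                     relative_change = unname(rel))),
            class = "heel_point_sensitivity")
}

#' @export
print.heel_point_sensitivity <- function(x, ...) {
  cat(sprintf("Heel-point sensitivity, offset (%g, %g, %g) m (|offset| = %.1f mm)\n",
              x$offset[1], x$offset[2], x$offset[3],
              1000 * sqrt(sum(x$offset^2))))
  d <- x$deltas
  keep <- d$variable %in% c("W", "W_X", "W_Y", "W_Z",
                            "dE_e", "dE_p", "dE_p_CS")
  print(transform(d[keep, ], relative_change_pct = 100 * relative_change),
        row.names = FALSE, digits = 3)
  invisible(x)
}
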