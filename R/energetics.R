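# Per-trial energetics: force-integral work and effective-mass models.

# Build the integration grid on the force time base over [t_a, t_b]:
# interior force samples plus linearly interpolated endpoint values.
force_grid <- function(grf, t_a, t_b) {
  inner <- which(grf$time > t_a & grf$time < t_b)
  tg <- c(t_a, grf$time[inner], t_b)
  list(t = tg, inner = inner)
}

#' Work done by the GRF over the heel-strike deformation
#'
#' Computes the force-integral estimate of the energy absorbed by the
#' foot-ankle system: the path integral of the ground reaction force
#' over the foot-ankle deformation, evaluated per component with the
#' trapezoidal rule on the force time base (the deformation, sampled at
#' the coarser kinematic rate, is linearly interpolated up to the force
#' base so the sharp impact transient is preserved in the integrand).
#' Negative work means energy absorbed by the foot.
#'
#' @param grf A [grf_series()].
#' @param track A [reconstruct_heel_track()] result.
#' @param t0 Contact onset (s).
#' @param t_e End of heel strike (s); must exceed `t0`.
#' @return Named list `W, W_X, W_Y, W_Z` (J), with `W = W_X + W_Y +
#'   W_Z` by construction.
#' @export
work_by_grf <- function(grf, track, t0, t_e) {
  stopifnot(inherits(grf, "grf_series"), inherits(track, "heel_track"))
  if (t_e <= t0)
    hs_stop("t_e must be after t0", "heelstrike_event_error",
            stage = "energetics")
  if (t0 < track$time[1] || t_e > track$time[length(track$time)])
    hs_stop("deformation does not cover [t0, t_e]",
            "heelstrike_sync_error", stage = "energetics")
  g <- force_grid(grf, t0, t_e)
  comp <- function(Fcol, k) {
    Fg <- interp1(grf$time, Fcol, g$t, "energetics")
    Sg <- interp1(track$time, track$S[, k], g$t, "energetics")
    n <- length(Fg)
    sum(0.5 * (Fg[-1] + Fg[-n]) * diff(Sg))
  }
  W_X <- comp(grf$F_X, 1)
  W_Y <- comp(grf$F_Y, 2)
  W_Z <- comp(grf$F_Z, 3)
  list(W = W_X + W_Y + W_Z, W_X = W_X, W_Y = W_Y, W_Z = W_Z)
}

#' Effective foot mass from the impulse-momentum balance
#'
#' The effective-mass model treats the decelerating part of the foot as
#' a point mass acted on by the vertical GRF and gravity.  Integrating
#' Newton's second law from `t_start` to `t_end` gives
#' `M = integral(F_Z dt) / (v_end - v_start + g (t_end - t_start))`.
#' Three variants of one formula: with `t_end = t_e` and `v_end = 0`
#' this is the improved-model mass `M_e`; with `t_end = t_p` and the
#' measured `v_end` it is `M_p`; with `t_end = t_p` and `v_end` forced
#' to zero it is the original-model mass `M_p_CS`.
#'
#' @param grf A [grf_series()]; impulse by trapezoidal integration of
#'   `F_Z` on the force base with interpolated endpoints.
#' @param v_start,v_end Vertical heel velocities (m/s) at the interval
#'   ends.
#' @param t_start,t_end Interval bounds (s).
#' @param g Gravitational acceleration (m/s^2).
#' @return Effective mass (kg).
#' @export
effective_mass <- function(grf, v_start, v_end, t_start, t_end, g = 9.81) {
  stopifnot(inherits(grf, "grf_series"))
  if (t_end <= t_start)
    hs_stop("t_end must be after t_start", "heelstrike_event_error",
            stage = "energetics")
  den <- v_end - v_start + g * (t_end - t_start)
  if (!is.finite(den) || den <= 0)
    hs_stop("non-positive denominator in the impulse-momentum balance: model assumption violated",
            "heelstrike_model_error", stage = "energetics")
  g1 <- force_grid(grf, t_start, t_end)
  Fg <- interp1(grf$time, grf$F_Z, g1$t, "energetics")
  pracma::trapz(g1$t, Fg) / den
}

#' Energy change of the effective mass
#'
#' `dE = 1/2 M (v_end^2 - v_start^2) + M g (z_end - z_start)`: the
#' change in kinetic plus potential energy of the effective mass, our
#' sign convention being the energy change OF the mass, negative when
#' energy is absorbed by the foot-ground contact.
#'
#' @param M Effective mass (kg), > 0.
#' @param v_start,v_end Vertical velocities (m/s).
#' @param z_start,z_end Vertical heel positions (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return Energy change (J).
#' @export
effective_mass_energy <- function(M, v_start, v_end, z_start, z_end,
                                  g = 9.81) {
  if (!is.finite(M) || M <= 0)
    hs_stop("effective mass must be positive", "heelstrike_input_error",
            stage = "energetics")
  0.5 * M * (v_end^2 - v_start^2) + M * g * (z_end - z_start)
}
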