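# Synthetic heel-strike trials: a point-mass viscoelastic ground
# contact with a full energy audit, rendered as raw force-plate
# channels and marker files so every pipeline stage can be tested
# against known ground truth.

#' Configuration of a synthetic heel-strike trial
#'
#' The effective foot mass touches down vertically at `v0` onto a
#' viscoelastic contact.  With `contact_exponent = 1` the contact is
#' Kelvin-Voigt, `F = k d + c dd/dt` for penetration `d`, clipped so it
#' never pulls; exponents above 1 give a Hertz-like law
#' `F = k d^n + c (dd/dt) d^(n-1)` whose force rises smoothly from
#' zero.  Horizontal heel drift and shear forces are prescribed (no
#' horizontal dynamics).  Markers ride on a rigid segment fixed to the
#' heel point.
#'
#' @param mass Effective foot mass `M_true` (kg).
#' @param stiffness Contact stiffness (N/m).
#' @param damping Contact damping (N s/m).
#' @param contact_exponent Contact-law exponent (1 = Kelvin-Voigt).
#' @param v0 Vertical touchdown velocity (m/s), negative (downward).
#' @param v_horiz Length-2 prescribed horizontal heel drift (m/s)
#'   during contact.
#' @param shear_stiffness,shear_damping Prescribed shear-force law
#'   coefficients: the rendered shear force opposing the drift is
#'   `-(k_s u + c_s du/dt)` for drift displacement `u`.
#' @param cop_local True heel-point offset (m): position of the heel
#'   contact point in the marker-cluster local frame at touchdown.
#' @param marker_offsets Optional list of two segment-frame 3-vectors
#'   from the heel point to led1 and led2; by default led1 is at
#'   `-cop_local` and led2 a distance `led_spacing` above it.
#' @param led_spacing Inter-LED distance (m).
#' @param segment_tilt Segment tilt about global X (degrees): a single
#'   value (constant) or length 2 (linear ramp over contact).
#' @param noise_marker_sd Marker noise SD per coordinate (m).
#' @param noise_channel_sd Force-channel noise SD (N).
#' @param sync_jitter Signed force-vs-kinematics synchronization error
#'   (s), magnitude at most 1 ms.
#' @param force_rate,kin_rate Sampling rates (Hz).
#' @param ode_step Integration step (s), at most `1/(10 force_rate)`.
#' @param lead_in Pre-contact recording time (s).
#' @param max_contact Contact-integration cap (s).
#' @param g Gravitational acceleration (m/s^2).
#' @param contact_point Global XY of the heel contact point at
#'   touchdown (m).
#' @param plate A [plate_geometry()].
#' @param seed Integer seed for the rendering noise.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mass = 8.5, stiffness = 23000, damping = 310,
                       contact_exponent = 1, v0 = -0.57,
                       v_horiz = c(0, 0),
                       shear_stiffness = 0, shear_damping = 0,
                       cop_local = c(0.01, -0.04, -0.12),
                       marker_offsets = NULL, led_spacing = 0.16,
                       segment_tilt = 0,
                       noise_marker_sd = 1e-4, noise_channel_sd = 0.25,
                       sync_jitter = 5e-4,
                       force_rate = 3000, kin_rate = 1295,
                       ode_step = 1e-5, lead_in = 0.1,
                       max_contact = 0.15, g = 9.81,
                       contact_point = c(0, 0),
                       plate = plate_geometry(force_rate = force_rate),
                       seed = 1L) {
  if (!(mass > 0 && stiffness > 0 && damping >= 0))
    hs_stop("require mass > 0, stiffness > 0, damping >= 0",
            "heelstrike_config_error", stage = "synthetic")
  if (v0 >= 0)
    hs_stop("v0 must be negative (downward touchdown): no contact otherwise",
            "heelstrike_config_error", stage = "synthetic")
  if (!(force_rate > 0 && kin_rate > 0))
    hs_stop("sampling rates must be positive",
            "heelstrike_config_error", stage = "synthetic")
  if (ode_step > 1 / (10 * force_rate))
    hs_stop("ode_step must be at most 1/(10 * force_rate)",
            "heelstrike_config_error", stage = "synthetic")
  if (abs(sync_jitter) > 1e-3)
    hs_stop("sync_jitter magnitude must be at most 1 ms",
            "heelstrike_config_error", stage = "synthetic")
  if (is.null(marker_offsets))
    marker_offsets <- list(-cop_local, -cop_local + c(0, 0, led_spacing))
  structure(list(mass = mass, stiffness = stiffness, damping = damping,
                 contact_exponent = contact_exponent, v0 = v0,
                 v_horiz = v_horiz, shear_stiffness = shear_stiffness,
                 shear_damping = shear_damping, cop_local = cop_local,
                 marker_offsets = marker_offsets,
                 led_spacing = led_spacing, segment_tilt = segment_tilt,
                 noise_marker_sd = noise_marker_sd,
                 noise_channel_sd = noise_channel_sd,
                 sync_jitter = sync_jitter, force_rate = force_rate,
                 kin_rate = kin_rate, ode_step = ode_step,
                 lead_in = lead_in, max_contact = max_contact, g = g,
                 contact_point = contact_point, plate = plate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Damping ratio of a synthetic configuration
#' @param cfg A [sim_config()].
#' @return `c / (2 sqrt(M k))`.
#' @export
damping_ratio <- function(cfg) {
  cfg$damping / (2 * sqrt(cfg$mass * cfg$stiffness))
}

#' Simulate the heel-impact dynamics
#'
#' Integrates `M z'' = -M g + F_c(z, z')` with fixed-step 4th-order
#' Runge-Kutta from `z(0) = 0`, `z'(0) = v0` until rebound lift-off
#' (`z > 0`) or `max_contact`.  The contact work on the mass and the
#' dissipated energy are accumulated as additional states with the
#' same integration stages, so the energy audit
#' `dKE + dPE = work_by_contact` holds to integration accuracy at
#' every output time.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `heel_impact_sim`: list with `solution`
#'   (data frame `t, z, zdot, F_c, delta, work, dissipated, stored`;
#'   times relative to touchdown), `truth` (list: `t_p_true`,
#'   `t_e_true`, `t_end`, `delta_te`, `work_te`, `dissipated_te`,
#'   `energy_residual_max`, `max_KE`), and `cfg`.
#' @export
simulate_heel_impact <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  M <- cfg$mass; k <- cfg$stiffness; cc <- cfg$damping
  nn <- cfg$contact_exponent; g <- cfg$g; h <- cfg$ode_step
  deriv <- function(z, zd) {
    delta <- -z
    if (delta >= 0) {   # contact from the touchdown instant itself
      dn1 <- if (nn == 1) 1 else delta^(nn - 1)
      Fraw <- k * delta * dn1 - cc * zd * dn1
      if (Fraw > 0) {
        return(c(zd, -g + Fraw / M, Fraw * zd, cc * zd^2 * dn1))
      }
    }
    c(zd, -g, 0, 0)
  }
  N <- ceiling(cfg$max_contact / h)
  z <- numeric(N + 1L); zd <- numeric(N + 1L)
  wk <- numeric(N + 1L); ds <- numeric(N + 1L)
  z[1] <- 0; zd[1] <- cfg$v0
  i <- 1L
  while (i <= N) {
    k1 <- deriv(z[i], zd[i])
    k2 <- deriv(z[i] + h / 2 * k1[1], zd[i] + h / 2 * k1[2])
    k3 <- deriv(z[i] + h / 2 * k2[1], zd[i] + h / 2 * k2[2])
    k4 <- deriv(z[i] + h * k3[1], zd[i] + h * k3[2])
    st <- (k1 + 2 * k2 + 2 * k3 + k4) / 6
    z[i + 1L] <- z[i] + h * st[1]
    zd[i + 1L] <- zd[i] + h * st[2]
    wk[i + 1L] <- wk[i] + h * st[3]
    ds[i + 1L] <- ds[i] + h * st[4]
    i <- i + 1L
    if (z[i] > 0) break   # rebound lift-off
  }
  keep <- seq_len(i)
  t <- (keep - 1L) * h
  z <- z[keep]; zd <- zd[keep]; wk <- wk[keep]; ds <- ds[keep]
  delta <- pmax(0, -z)
  dn1 <- if (nn == 1) rep(1, length(delta)) else delta^(nn - 1)
  F_c <- ifelse(z <= 0, pmax(0, (k * delta - cc * zd) * dn1), 0)
  stored <- k * delta^(nn + 1) / (nn + 1)
  ip <- which.max(F_c)
  up <- which(zd[-length(zd)] < 0 & zd[-1] >= 0)[1]
  t_e_true <- if (is.na(up)) NA_real_ else
    t[up] + (0 - zd[up]) * (t[up + 1] - t[up]) / (zd[up + 1] - zd[up])
  KE <- 0.5 * M * zd^2
  resid <- (KE - 0.5 * M * cfg$v0^2) + M * g * z - wk
  at_te <- function(x) if (is.na(t_e_true)) NA_real_ else
    stats::approx(t, x, xout = t_e_true)$y
  truth <- list(t_p_true = t[ip], t_e_true = t_e_true,
                t_end = t[length(t)],
                delta_te = at_te(delta), work_te = at_te(wk),
                dissipated_te = at_te(ds),
                energy_residual_max = max(abs(resid)), max_KE = max(KE))
  structure(list(solution = data.frame(t = t, z = z, zdot = zd,
                                       F_c = F_c, delta = delta,
                                       work = wk, dissipated = ds,
                                       stored = stored),
                 truth = truth, cfg = cfg),
            class = "heel_impact_sim")
}

#' Forward-render a GRF and COP onto the eight plate channels
#'
#' Exact inverse of [reduce_channels()]: splits the vertical load
#' bilinearly among the four sensors at the sensor-plane-projected
#' COP and the shear evenly between the paired channels.  Samples with
#' `F_Z = 0` render as all-zero channels.
#'
#' @param time Sample times (s).
#' @param F_X,F_Y,F_Z Force on the foot (N).
#' @param cop_X,cop_Y Global COP at the plate surface (m).
#' @param geom A [plate_geometry()].
#' @return A [channel_record()].
#' @export
grf_to_channels <- function(time, F_X, F_Y, F_Z, cop_X, cop_Y, geom) {
  Xp <- cop_X - geom$origin_offset[1]
  Yp <- cop_Y - geom$origin_offset[2]
  on <- F_Z > 0
  xs <- ifelse(on, Xp - geom$az0 * F_X / pmax(F_Z, 1e-12), 0)
  ys <- ifelse(on, Yp - geom$az0 * F_Y / pmax(F_Z, 1e-12), 0)
  if (any(on & (abs(xs) > geom$a | abs(ys) > geom$b)))
    hs_stop("COP outside the sensor rectangle",
            "heelstrike_render_error", stage = "synthetic")
  u <- ifelse(on, (xs + geom$a) / (2 * geom$a), 0.5)
  v <- ifelse(on, (ys + geom$b) / (2 * geom$b), 0.5)
  Fz <- ifelse(on, F_Z, 0)
  channel_record(time, list(
    fx12 = ifelse(on, F_X / 2, 0), fx34 = ifelse(on, F_X / 2, 0),
    fy14 = ifelse(on, F_Y / 2, 0), fy23 = ifelse(on, F_Y / 2, 0),
    fz1 = Fz * (1 - u) * v, fz2 = Fz * u * v,
    fz3 = Fz * u * (1 - v), fz4 = Fz * (1 - u) * (1 - v)))
}

#' Render a simulated impact as raw force-plate channels
#'
#' Samples the contact force at the force rate (time-shifted by the
#' synchronization jitter), splits the vertical load bilinearly among
#' the four sensors at the sensor-plane-projected COP, splits shear
#' evenly between the paired channels, and adds seeded Gaussian
#' channel noise.
#'
#' @param sim A [simulate_heel_impact()] result.
#' @param noise_channel_sd,sync_jitter Overrides of the corresponding
#'   `sim$cfg` values (useful for rendering the same solution with and
#'   without measurement error).
#' @return A [channel_record()] covering `lead_in` plus the contact.
#' @export
render_plate_channels <- function(sim, noise_channel_sd = NULL,
                                  sync_jitter = NULL) {
  stopifnot(inherits(sim, "heel_impact_sim"))
  cfg <- sim$cfg
  if (is.null(noise_channel_sd)) noise_channel_sd <- cfg$noise_channel_sd
  if (is.null(sync_jitter)) sync_jitter <- cfg$sync_jitter
  sol <- sim$solution
  t_end <- sim$truth$t_end
  time <- seq(0, cfg$lead_in + t_end, by = 1 / cfg$force_rate)
  tau <- time - cfg$lead_in - sync_jitter
  # Resampling the continuous-time contact force to the plate rate:
  # band-limit on the fine integration grid first (a Kelvin-Voigt
  # contact force steps at touchdown; point-sampling a step aliases),
  # mirroring the finite bandwidth of a real charge-amplifier chain.
  h <- cfg$ode_step
  npre <- as.integer(round(0.01 / h))
  tf <- c((-npre:-1) * h, sol$t)
  fine <- function(x_contact) {
    x <- c(numeric(npre), x_contact)
    if (all(x == 0)) return(x)
    zero_phase_lowpass(x, cutoff = 0.4 * cfg$force_rate, rate = 1 / h)
  }
  shear <- function(axis) {
    v <- cfg$v_horiz[axis]
    raw <- -(cfg$shear_stiffness * v * pmin(sol$t, t_end) +
               cfg$shear_damping * v)
    raw[sol$F_c <= 0] <- 0
    raw
  }
  samp <- function(xf) stats::approx(tf, xf, xout = tau, rule = 2)$y
  F_Z <- samp(fine(sol$F_c))
  F_X <- samp(fine(shear(1)))
  F_Y <- samp(fine(shear(2)))
  tauc <- pmin(pmax(tau, 0), t_end)
  cop_X <- cfg$contact_point[1] + cfg$v_horiz[1] * tauc
  cop_Y <- cfg$contact_point[2] + cfg$v_horiz[2] * tauc
  rec <- grf_to_channels(time, F_X, F_Y, F_Z, cop_X, cop_Y, cfg$plate)
  if (noise_channel_sd > 0)
    for (ch in channel_names)
      rec[[ch]] <- rec[[ch]] + stats::rnorm(length(time), 0,
                                            noise_channel_sd)
  rec
}

#' Render a simulated impact as a two-LED marker record
#'
#' The heel point follows the simulated vertical motion (descending at
#' `v0` before touchdown) plus the prescribed horizontal drift; the
#' markers sit at fixed offsets in a rigid segment frame tilted about
#' global X by `segment_tilt` (constant, or ramped linearly over
#' contact).  Seeded Gaussian noise is added per coordinate.
#'
#' @param sim A [simulate_heel_impact()] result.
#' @param noise_marker_sd Override of `sim$cfg$noise_marker_sd`.
#' @return A [marker_series()] on the kinematic time base.
#' @export
render_markers <- function(sim, noise_marker_sd = NULL) {
  stopifnot(inherits(sim, "heel_impact_sim"))
  cfg <- sim$cfg
  if (is.null(noise_marker_sd)) noise_marker_sd <- cfg$noise_marker_sd
  sol <- sim$solution
  t_end <- sim$truth$t_end
  time <- seq(0, cfg$lead_in + t_end, by = 1 / cfg$kin_rate)
  tau <- time - cfg$lead_in
  tauc <- pmin(pmax(tau, 0), t_end)
  z_heel <- ifelse(tau < 0, cfg$v0 * tau,
                   stats::approx(sol$t, sol$z, xout = tauc)$y)
  heel <- cbind(cfg$contact_point[1] + cfg$v_horiz[1] * tauc,
                cfg$contact_point[2] + cfg$v_horiz[2] * tauc,
                z_heel)
  th <- if (length(cfg$segment_tilt) == 1L)
    rep(cfg$segment_tilt, length(time)) else
    cfg$segment_tilt[1] + (cfg$segment_tilt[2] - cfg$segment_tilt[1]) *
      tauc / t_end
  th <- th * pi / 180
  place <- function(off) {
    led <- heel
    led[, 1] <- led[, 1] + off[1]
    led[, 2] <- led[, 2] + cos(th) * off[2] - sin(th) * off[3]
    led[, 3] <- led[, 3] + sin(th) * off[2] + cos(th) * off[3]
    led
  }
  led1 <- place(cfg$marker_offsets[[1]])
  led2 <- place(cfg$marker_offsets[[2]])
  if (noise_marker_sd > 0) {
    led1 <- led1 + matrix(stats::rnorm(length(led1), 0, noise_marker_sd),
                          ncol = 3)
    led2 <- led2 + matrix(stats::rnorm(length(led2), 0, noise_marker_sd),
                          ncol = 3)
  }
  marker_series(time, led1, led2)
}

#' Simulate and render one complete synthetic trial
#'
#' @param cfg A [sim_config()].  `cfg$seed` seeds the rendering noise.
#' @return An object of class `heel_trial`: list with `channels`
#'   (raw force record), `markers`, `sim` (the
#'   [simulate_heel_impact()] result), and `truth` -- the simulator
#'   ground truth with event times on the trial clock (`touchdown`,
#'   `t_p`, `t_e`), the true mass, the contact work and dissipated
#'   energy at `t_e`, and the true local heel point.
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- simulate_heel_impact(cfg)
  set.seed(cfg$seed)
  channels <- render_plate_channels(sim)
  markers <- render_markers(sim)
  tr <- sim$truth
  truth <- list(touchdown = cfg$lead_in,
                t_p = cfg$lead_in + tr$t_p_true,
                t_e = cfg$lead_in + tr$t_e_true,
                M_true = cfg$mass, stiffness = cfg$stiffness,
                damping = cfg$damping, damping_ratio = damping_ratio(cfg),
                v0 = cfg$v0, delta_te = tr$delta_te,
                work_te = tr$work_te, dissipated_te = tr$dissipated_te,
                r_H_local = cfg$cop_local, sync_jitter = cfg$sync_jitter)
  structure(list(channels = channels, markers = markers, sim = sim,
                 truth = truth, cfg = cfg),
            class = "heel_trial")
}

#' Default parameter ranges for the fixture study
#'
#' Subject-level parameters are drawn uniformly from these ranges:
#' body mass (kg); effective foot mass as a fraction of body mass;
#' the undamped quarter-period of the contact (s), from which the
#' stiffness follows as `k = M (pi / (2 T))^2`; the damping ratio; and
#' the touchdown velocity (m/s) with a per-trial jitter SD.
#'
#' @return Named list of ranges.
#' @export
fixture_ranges <- function() {
  list(body_mass = c(60, 95), mass_fraction = c(0.09, 0.13),
       quarter_period = c(0.025, 0.038), zeta = c(0.25, 0.45),
       v0 = c(-0.78, -0.39), v0_sd = 0.05)
}

#' Generate a deterministic multi-subject fixture study
#'
#' Emulates an instrumented-gait study: `n_subjects` subjects with
#' subject-specific contact parameters, `n_trials` trials each with
#' trial-level touchdown-velocity jitter and synchronization jitter.
#' Deterministic given `seed` (all parameters are drawn before any
#' trial is rendered).
#'
#' @param n_subjects,n_trials Study size.
#' @param ranges Parameter ranges, see [fixture_ranges()].
#' @param seed Integer seed.
#' @param dir Optional directory: when given, force/marker CSVs and a
#'   `truth.json` manifest are written there.
#' @param noise Logical: render with measurement noise (marker noise,
#'   channel noise, sync jitter) or noiselessly.
#' @return List with `trials` (list of [simulate_trial()] results) and
#'   `manifest` (data frame of per-trial truth).
#' @export
make_fixture_study <- function(n_subjects = 12, n_trials = 10,
                               ranges = fixture_ranges(), seed = 1L,
                               dir = NULL, noise = TRUE) {
  set.seed(seed)
  draw <- function(r) stats::runif(1, r[1], r[2])
  params <- list()
  for (s in seq_len(n_subjects)) {
    bm <- draw(ranges$body_mass)
    M <- draw(ranges$mass_fraction) * bm
    Tq <- draw(ranges$quarter_period)
    k <- M * (pi / (2 * Tq))^2
    zeta <- draw(ranges$zeta)
    v0s <- draw(ranges$v0)
    for (j in seq_len(n_trials)) {
      v0 <- min(v0s + stats::rnorm(1, 0, ranges$v0_sd), -0.2)
      params[[length(params) + 1L]] <- list(
        subject = s, trial = j, body_mass = bm, mass = M,
        stiffness = k, damping = 2 * zeta * sqrt(M * k), zeta = zeta,
        v0 = v0,
        # touchdown is never phase-locked to the sampling clocks
        lead_in = 0.1 + stats::runif(1, 0, 1 / 3000),
        sync_jitter = if (noise) stats::runif(1, -1e-3, 1e-3) else 0,
        seed = sample.int(2^30, 1))
    }
  }
  trials <- lapply(params, function(p) {
    cfg <- sim_config(mass = p$mass, stiffness = p$stiffness,
                      damping = p$damping, v0 = p$v0,
                      lead_in = p$lead_in,
                      sync_jitter = p$sync_jitter,
                      noise_marker_sd = if (noise) 1e-4 else 0,
                      noise_channel_sd = if (noise) 0.25 else 0,
                      seed = p$seed)
    simulate_trial(cfg)
  })
  manifest <- do.call(rbind, lapply(seq_along(params), function(i) {
    p <- params[[i]]; tr <- trials[[i]]$truth
    data.frame(subject = p$subject, trial = p$trial, seed = p$seed,
               body_mass = p$body_mass, M_true = p$mass,
               stiffness = p$stiffness, damping = p$damping,
               zeta = p$zeta, v0 = p$v0, sync_jitter = p$sync_jitter,
               t_p_true = tr$t_p, t_e_true = tr$t_e,
               delta_te = tr$delta_te, work_te = tr$work_te,
               force_file = sprintf("s%02d_t%02d_force.csv",
                                    p$subject, p$trial),
               marker_file = sprintf("s%02d_t%02d_markers.csv",
                                     p$subject, p$trial))
  }))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(trials)) {
      write_force_csv(trials[[i]]$channels,
                      file.path(dir, manifest$force_file[i]))
      write_marker_csv(trials[[i]]$markers,
                       file.path(dir, manifest$marker_file[i]))
    }
    writeLines(jsonlite::toJSON(manifest, digits = I(12),
                                dataframe = "rows"),
               file.path(dir, "truth.json"))
  }
  list(trials = trials, manifest = manifest)
}
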