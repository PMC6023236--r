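# Force-integral work and effective-mass model quantities.

make_track <- function(tm, S_Z, t0 = tm[1]) {
  n <- length(tm)
  S <- cbind(0, 0, S_Z)
  R_H <- sweep(S, 2, c(0, 0, 0.0), "+")
  structure(list(time = tm, r_H = c(0, 0, 0), R_H = R_H, S = S,
                 Zdot_H = heelstrike:::grad1(R_H[, 3], tm), t0 = t0),
            class = "heel_track")
}

test_that("trapezoidal work is exact for linear and constant integrands", {
  tm <- seq(0, 0.03, by = 1 / 3000)
  # F_Z ramps 0 -> 200 N while S_Z goes 0 -> -0.01 m, both linear in t
  grf <- grf_series(tm, 0 * tm, 0 * tm, 200 * tm / 0.03, NA * tm, NA * tm,
                    !is.na(tm))
  trk <- make_track(tm, -0.01 * tm / 0.03)
  w <- work_by_grf(grf, trk, 0, 0.03)
  expect_equal(w$W_Z, -1.0, tolerance = 1e-12)
  expect_equal(w$W_X, 0); expect_equal(w$W_Y, 0)

  grf2 <- grf_series(tm, 0 * tm, 0 * tm, 0 * tm + 100, NA * tm, NA * tm,
                     !is.na(tm))
  trk2 <- make_track(tm, -0.02 * tm / 0.03)
  w2 <- work_by_grf(grf2, trk2, 0, 0.03)
  expect_equal(w2$W_Z, -2.0, tolerance = 1e-12)
  expect_equal(w2$W, w2$W_X + w2$W_Y + w2$W_Z, tolerance = 1e-12)

  expect_error(work_by_grf(grf, trk, 0.03, 0.01),
               class = "heelstrike_event_error")
})

test_that("effective mass matches the closed-form impulse balance", {
  tm <- seq(0, 0.03, by = 1e-4)
  grf <- grf_series(tm, 0 * tm, 0 * tm, 0 * tm + 100, NA * tm, NA * tm,
                    !is.na(tm))
  M <- effective_mass(grf, -0.57, 0, 0, 0.03)
  expect_equal(M, 3 / (0.57 + 9.81 * 0.03), tolerance = 1e-9)

  # static limit: constant F = M* g with no velocity change returns M*
  Mstar <- 70
  grf_s <- grf_series(tm, 0 * tm, 0 * tm, 0 * tm + Mstar * 9.81,
                      NA * tm, NA * tm, !is.na(tm))
  expect_equal(effective_mass(grf_s, -0.3, -0.3, 0, 0.03), Mstar,
               tolerance = 1e-9)

  # non-positive denominator is a model-assumption error
  expect_error(effective_mass(grf, -0.1, -0.6, 0, 0.03),
               class = "heelstrike_model_error")
})

test_that("effective-mass energy change follows the adopted sign convention", {
  # identity: no velocity or height change
  expect_equal(effective_mass_energy(5, -0.4, -0.4, 0.1, 0.1), 0)
  # the in-text worked example: mean effective mass, touchdown velocity
  # and maximal compression give -2.46 J
  M <- 0.111 * 76.7
  expect_equal(effective_mass_energy(M, -0.57, 0, 0, -0.0129),
               -2.46, tolerance = 0.005)
  expect_error(effective_mass_energy(-1, -0.5, 0, 0, 0),
               class = "heelstrike_input_error")
})

test_that("force-integral work matches the simulator energy audit", {
  tr <- base_trial()
  fit <- base_fit()
  sol <- tr$sim$solution
  cfgs <- tr$cfg
  # the contact energy balance runs from touchdown; the detected t0 may
  # sit one zero-force sample earlier
  tau <- c(max(fit$events$t0 - tr$truth$touchdown, 0),
           fit$events$t_e - tr$truth$touchdown)
  KEPE <- function(t) {
    z <- approx(sol$t, sol$z, xout = t)$y
    zd <- approx(sol$t, sol$zdot, xout = t)$y
    0.5 * cfgs$mass * zd^2 + cfgs$mass * cfgs$g * z
  }
  truthW <- KEPE(tau[2]) - KEPE(tau[1])
  expect_equal(fit$energetics$W, truthW, tolerance = 0.01)
  # point-mass work-energy theorem: dE_e equals W_Z within 2%
  expect_equal(fit$energetics$dE_e / fit$energetics$W_Z, 1,
               tolerance = 0.02)
})

test_that("component works sum to the total and converge with rate", {
  fit <- base_fit()
  e <- fit$energetics
  expect_equal(e$W, e$W_X + e$W_Y + e$W_Z, tolerance = 1e-9)

  # doubling the force sampling rate changes the integral by < 0.1%
  # (same trial, same track and events; only the force base refines;
  # smooth contact law, so the trapezoid is in its second-order regime)
  cfgh <- noiseless_cfg(contact_exponent = 1.5, stiffness = 4e5,
                        damping = 450)
  trh <- cached("hertz_trial", simulate_trial(cfgh))
  fith <- heel_strike(trh$channels, trh$markers)
  sim6 <- trh$sim
  sim6$cfg$force_rate <- 6000
  grf6 <- reduce_channels(render_plate_channels(sim6), plate_geometry())
  grf3 <- reduce_channels(trh$channels, plate_geometry())
  w3 <- work_by_grf(grf3, fith$track, fith$events$t0, fith$events$t_e)
  w6 <- work_by_grf(grf6, fith$track, fith$events$t0, fith$events$t_e)
  expect_equal(w6$W / w3$W, 1, tolerance = 1e-3)
})

test_that("shear drift produces the prescribed horizontal work", {
  cfg <- noiseless_cfg(v_horiz = c(0.05, 0.12), shear_stiffness = 4000,
                       shear_damping = 40)
  tr <- cached("shear_trial", simulate_trial(cfg))
  fit <- heel_strike(tr$channels, tr$markers, body_mass = 76.7)
  # truth: integral of -(k_s u + c_s v) v dt from touchdown to t_e
  te <- fit$events$t_e - tr$truth$touchdown
  wtruth <- function(v) -(cfg$shear_stiffness * v^2 * te^2 / 2 +
                            cfg$shear_damping * v^2 * te)
  expect_equal(fit$energetics$W_X, wtruth(0.05), tolerance = 0.05)
  expect_equal(fit$energetics$W_Y, wtruth(0.12), tolerance = 0.05)
  expect_lt(fit$energetics$W_X, 0)
  expect_lt(fit$energetics$W_Y, 0)
})

test_that("trial orchestration fails informatively without contact", {
  tm <- seq(0, 0.3, by = 1 / 3000)
  rec <- grf_to_channels(tm, 0 * tm, 0 * tm, 0 * tm, 0 * tm, 0 * tm,
                         plate_geometry())
  tr <- base_trial()
  expect_error(heel_strike(rec, tr$markers),
               class = "heelstrike_nocontact_error")
})

test_that("a full trial fit has absorbed energy and ordered events", {
  fit <- base_fit()
  e <- fit$energetics
  expect_lt(e$W_Z, 0)
  expect_lt(e$dE_e, 0)
  expect_gt(fit$events$t_p, fit$events$t0)
  expect_gt(fit$events$t_e, fit$events$t_p)   # damped trial
  expect_equal(e$M_e_pct, 100 * e$M_e / 76.7)
  expect_length(fit$flags, 0)
})
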