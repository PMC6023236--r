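# Local frames, heel-point estimation, heel track and its events.

rot_x <- function(deg) {
  th <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
}

test_that("local frames match analytic rotations", {
  tm <- c(0, 1e-3)
  m <- marker_series(tm, rbind(c(0, 0, 0), c(0, 0, 0)),
                     rbind(c(0, 0, 0.16), c(0, 0, 0.16)))
  fr <- build_local_frames(m)
  expect_equal(fr$rotation[, , 1], diag(3), tolerance = 1e-12)

  led2 <- t(rot_x(10) %*% c(0, 0, 0.16))
  m10 <- marker_series(tm, rbind(c(0, 0, 0), c(0, 0, 0)),
                       rbind(led2, led2))
  fr10 <- build_local_frames(m10)
  expect_equal(fr10$rotation[, , 1], rot_x(10), tolerance = 1e-12)
  expect_equal(fr10$rotation[, 1, 1], c(1, 0, 0), tolerance = 1e-12)
})

test_that("frames are orthonormal with local y in the progression plane", {
  set.seed(11)
  tm <- seq(0, 0.2, by = 1 / 1295)
  n <- length(tm)
  led1 <- cbind(0.01 * sin(5 * tm), 1.3 * tm, 0.1 + 0.02 * cos(3 * tm))
  ang <- 5 * sin(2 * pi * tm)          # wobble about X, degrees
  led2 <- led1 + t(sapply(ang, function(a) rot_x(a) %*% c(0, 0, 0.16)))
  fr <- build_local_frames(marker_series(tm, led1, led2))
  for (i in seq(1, n, by = 37)) {
    R <- fr$rotation[, , i]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_gt(det(R), 0)
    expect_equal(R[1, 2], 0, tolerance = 1e-12)   # y has no global-X part
    expect_gt(R[2, 2], 0)                         # y is anterior-positive
    expect_equal(R[, 3], (led2[i, ] - led1[i, ]) / 0.16,
                 tolerance = 1e-9)
  }
})

test_that("degenerate marker geometry raises a geometry error", {
  tm <- c(0, 1e-3)
  same <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(build_local_frames(
    suppressWarnings(marker_series(tm, same, same))),
    class = "heelstrike_geometry_error")
  along_x <- rbind(c(0.16, 0, 0), c(0.16, 0, 0))
  expect_error(build_local_frames(
    suppressWarnings(marker_series(tm, same, along_x))),
    class = "heelstrike_geometry_error")
})

test_that("COP localization handles static and translated frames", {
  tm <- seq(0, 0.1, by = 1 / 1295)
  tf <- seq(0, 0.1, by = 1 / 3000)
  one <- rep(1, length(tf))
  grf <- grf_series(tf, 0 * one, 0 * one, 100 * one, 0.3 * one,
                    0.5 * one)
  fr <- static_frames(tm, c(0, 0, 0.1))
  lc <- localize_cop(fr, grf)
  expect_equal(unique(round(lc$x, 12)), 0.3)
  expect_equal(unique(round(lc$y, 12)), 0.5)
  expect_equal(unique(round(lc$z, 12)), -0.1)

  fr2 <- static_frames(tm, c(0.1, 0, 0.1))
  lc2 <- localize_cop(fr2, grf)
  expect_equal(unique(round(lc2$x, 12)), 0.2)
})

test_that("heel point is the windowed median and is outlier-robust", {
  grf <- triangle_grf()
  tm <- seq(0.09, 0.16, by = 1 / 1295)
  lc <- data.frame(time = tm,
                   x = rep(0.01, length(tm)),
                   y = rep(-0.03, length(tm)),
                   z = rep(-0.06, length(tm)))
  class(lc) <- c("local_cop", "data.frame")
  r <- estimate_heel_point(lc, grf, 0.115)
  expect_equal(as.numeric(r), c(0.01, -0.03, -0.06), tolerance = 1e-12)
  w <- attr(r, "window")
  expect_equal(unname(0.115 - w["start"]), unname(w["end"] - 0.115),
               tolerance = 1e-9)     # peak is the window midpoint

  lc_out <- lc
  lc_out$z[40] <- 5                  # one wild sample inside the window
  r2 <- estimate_heel_point(lc_out, grf, 0.115)
  expect_equal(as.numeric(r2), as.numeric(r), tolerance = 1e-12)
})

test_that("heel track is exact for static and uniformly moving frames", {
  tm <- seq(0, 0.1, by = 1 / 1295)
  fr <- static_frames(tm)
  trk <- reconstruct_heel_track(fr, c(0.01, -0.03, -0.06), 0.02)
  expect_true(all(abs(trk$S) < 1e-14))
  expect_true(all(abs(trk$Zdot_H) < 1e-12))

  n <- length(tm)
  fr2 <- static_frames(tm)
  fr2$origin[, 3] <- 0.1 - 0.5 * tm
  trk2 <- reconstruct_heel_track(fr2, c(0, 0, -0.06), 0.02)
  expect_equal(trk2$Zdot_H[2:(n - 1)], rep(-0.5, n - 2), tolerance = 1e-9)
  expect_error(reconstruct_heel_track(fr2, c(0, 0, 0), 1.0),
               class = "heelstrike_sync_error")
})

test_that("deformation end matches the analytic velocity zero", {
  tm <- seq(0, 0.12, by = 1 / 1295)
  fr <- static_frames(tm)
  fr$origin[, 3] <- 0.1 - 0.01 * sin(pi * tm / 0.06)
  trk <- reconstruct_heel_track(fr, c(0, 0, 0), 0)
  expect_equal(detect_deformation_end(trk, 0), 0.03, tolerance = 1e-4)

  # no crossing within 100 ms
  fr2 <- static_frames(tm)
  fr2$origin[, 3] <- 0.1 - 0.5 * tm
  trk2 <- reconstruct_heel_track(fr2, c(0, 0, 0), 0)
  expect_error(detect_deformation_end(trk2, 0),
               class = "heelstrike_event_error")
})

test_that("simulator truth is recovered: tilt, heel point, velocity, t_e", {
  # constant 5-degree segment tilt, raw markers, no noise
  tr5 <- cached("tilt5_trial",
                simulate_trial(noiseless_cfg(segment_tilt = 5)))
  fr <- build_local_frames(tr5$markers)
  expect_equal(fr$rotation[, , 10], rot_x(5), tolerance = 1e-9)

  # pure translation: local-x/y heel point to 0.1 mm; z biased by at
  # most the (surface-COP vs descending-frame) penetration
  tr <- base_trial()
  fit <- base_fit()
  expect_lt(abs(fit$r_H[1] - tr$truth$r_H_local[1]), 1e-4)
  expect_lt(abs(fit$r_H[2] - tr$truth$r_H_local[2]), 1e-4)
  expect_lt(abs(fit$r_H[3] - tr$truth$r_H_local[3]),
            max(tr$sim$solution$delta) + 1e-4)

  # with instrument-level marker noise the lateral/anterior error stays
  # under 0.5 mm
  trn <- cached("noisy_trial", simulate_trial(sim_config(seed = 5)))
  fitn <- heel_strike(trn$channels, trn$markers, body_mass = 76.7)
  expect_lt(abs(fitn$r_H[1] - trn$truth$r_H_local[1]), 5e-4)
  expect_lt(abs(fitn$r_H[2] - trn$truth$r_H_local[2]), 5e-4)

  # touchdown velocity and end of heel strike
  expect_lt(abs(fit$energetics$Zdot_t0 - (-0.57)), 0.02)
  expect_lt(abs(fit$events$t_e - tr$truth$t_e), 1 / 1295)

  # maximal compression occurs at t_e
  i_max <- which.min(fit$track$S[, 3])
  expect_lt(abs(fit$track$time[i_max] - fit$events$t_e), 1.5 / 1295)
})
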