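# Shared fixtures: simulations are cached so each is integrated once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

noiseless_cfg <- function(...) {
  sim_config(noise_marker_sd = 0, noise_channel_sd = 0, sync_jitter = 0,
             ...)
}

# Default damped trial (zeta ~ 0.35) without measurement error.
base_trial <- function() cached("base_trial",
                                simulate_trial(noiseless_cfg()))

base_fit <- function() cached("base_fit", {
  tr <- base_trial()
  heel_strike(tr$channels, tr$markers, body_mass = 76.7)
})

undamped_trial <- function() cached("undamped_trial",
                                    simulate_trial(noiseless_cfg(damping = 0)))

undamped_fit <- function() cached("undamped_fit", {
  tr <- undamped_trial()
  heel_strike(tr$channels, tr$markers, body_mass = 76.7)
})

# Closed-form solution of the in-contact linear viscoelastic phase
# (valid until the contact force would clip):
#   z'' + 2 zeta w z' + w^2 z = -g,  z(0) = 0,  z'(0) = v0.
osc_closed_form <- function(t, M, k, c, v0, g = 9.81) {
  w <- sqrt(k / M)
  zeta <- c / (2 * sqrt(M * k))
  stopifnot(zeta < 1)
  wd <- w * sqrt(1 - zeta^2)
  x0 <- g / w^2                       # offset from equilibrium at t = 0
  A <- x0
  B <- (v0 + zeta * w * x0) / wd
  e <- exp(-zeta * w * t)
  x <- e * (A * cos(wd * t) + B * sin(wd * t))
  xd <- e * ((B * wd - zeta * w * A) * cos(wd * t) -
               (A * wd + zeta * w * B) * sin(wd * t))
  list(z = x - x0, zdot = xd)
}

# First instant of zero vertical velocity of the closed-form solution.
osc_t_e <- function(M, k, c, v0, g = 9.81) {
  f <- function(t) osc_closed_form(t, M, k, c, v0, g)$zdot
  lo <- 1e-5
  hi <- lo
  while (f(hi) < 0) hi <- hi * 1.5
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# Static frame series (identity rotation) at a fixed origin.
static_frames <- function(time, origin = c(0, 0, 0.1)) {
  n <- length(time)
  rot <- array(diag(3), dim = c(3, 3, n))
  structure(list(time = time, rotation = rot,
                 origin = matrix(origin, n, 3, byrow = TRUE)),
            class = "frame_series")
}

# grf_series with a triangular vertical pulse (for event/window tests).
triangle_grf <- function(t0 = 0.1, t_peak = 0.115, t_off = 0.14,
                         peak = 600, rate = 3000, t_max = 0.2) {
  time <- seq(0, t_max, by = 1 / rate)
  F_Z <- ifelse(time <= t0 | time >= t_off, 0,
                ifelse(time <= t_peak, peak * (time - t0) / (t_peak - t0),
                       peak * (t_off - time) / (t_off - t_peak)))
  grf_series(time, 0 * time, 0 * time, F_Z,
             ifelse(F_Z >= 10, 0.0, NA), ifelse(F_Z >= 10, 0.0, NA))
}
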