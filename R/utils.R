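# Internal helpers: classed conditions, interpolation, integration.

# All package errors carry a condition class so callers (and the trial
# orchestrator) can react to the failure mode, not the message text.
hs_stop <- function(msg, class, stage = NULL, call = sys.call(-1)) {
  if (!is.null(stage)) msg <- sprintf("[%s] %s", stage, msg)
  stop(errorCondition(msg, class = c(class, "heelstrike_error"),
                      call = call, stage = stage))
}

hs_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "heelstrike_warning")))
}

# Linear interpolation that refuses to extrapolate.
interp1 <- function(x, y, xout, stage = "interp") {
  if (any(xout < x[1] - 1e-12) || any(xout > x[length(x)] + 1e-12))
    hs_stop("query time outside the covered range",
            "heelstrike_sync_error", stage = stage)
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

# Central-difference gradient on a (possibly non-uniform) time base,
# one-sided at the ends.  Exact for signals linear in time.
grad1 <- function(y, t) {
  n <- length(y)
  if (n < 3L)
    hs_stop("need at least 3 samples for a gradient",
            "heelstrike_input_error")
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  i <- 2:(n - 1)
  g[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  g
}

check_time <- function(time, stage, min_n = 1L) {
  if (length(time) < min_n || any(!is.finite(time)))
    hs_stop("time base must be finite and non-empty",
            "heelstrike_input_error", stage = stage)
  if (any(diff(time) <= 0))
    hs_stop("time must be strictly increasing",
            "heelstrike_input_error", stage = stage)
  invisible(TRUE)
}

# Fill interior NA runs of length <= max_run by linear interpolation;
# longer runs (or NA at the edges) are a data error.
fill_gaps <- function(x, max_run = 5L, column = "signal") {
  na <- is.na(x)
  if (!any(na)) return(list(x = x, filled = 0L))
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- which(r$values)
  for (j in bad) {
    if (r$lengths[j] > max_run || starts[j] == 1L || ends[j] == length(x))
      hs_stop(sprintf(
        "column '%s': NaN/NA run of %d samples at %d..%d exceeds the %d-sample gap limit",
        column, r$lengths[j], starts[j], ends[j], max_run),
        "heelstrike_data_error")
  }
  idx <- which(!na)
  x[na] <- stats::approx(idx, x[idx], xout = which(na))$y
  list(x = x, filled = sum(na))
}
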