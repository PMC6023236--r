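# Zero-phase low-pass filtering for marker kinematics.

#' Zero-phase Butterworth low-pass filter
#'
#' Applies a Butterworth low-pass filter forward and then backward in
#' time, so the net phase response is zero and event timings are
#' preserved.  The effective magnitude response is the squared
#' single-pass response (a 2nd-order design acts as an effective
#' 4th-order zero-phase filter).  Edges are handled by odd-reflection
#' padding of at least three filter lengths, so transients from the
#' filter start-up do not reach the retained samples.
#'
#' @param x Uniformly sampled signal.
#' @param cutoff Low-pass cutoff frequency (Hz).
#' @param rate Sampling rate (Hz); must exceed `2 * cutoff`.
#' @param order Butterworth order of each pass (default 2).
#' @return Filtered signal, same length as `x`.
#' @export
zero_phase_lowpass <- function(x, cutoff = 100, rate, order = 2) {
  if (missing(rate) || rate <= 2 * cutoff)
    hs_stop("sampling rate must exceed twice the cutoff",
            "heelstrike_input_error", stage = "kinematics")
  n <- length(x)
  npad <- max(3L * (order + 1L), ceiling(8 * rate / cutoff))
  if (n <= npad + 1L)
    hs_stop(sprintf("series of %d samples is shorter than the %d-sample edge padding",
                    n, npad),
            "heelstrike_input_error", stage = "kinematics")
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  pre <- 2 * x[1] - x[(npad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- c(pre, x, post)
  y <- as.numeric(signal::filter(bf$b, bf$a, y))
  y <- rev(as.numeric(signal::filter(bf$b, bf$a, rev(y))))
  y[(npad + 1L):(npad + n)]
}

# Squared magnitude response of the zero-phase filter at frequency f,
# from the digital coefficients themselves (used as a test oracle and
# for documentation plots).
butter_zero_phase_gain <- function(f, cutoff, rate, order = 2) {
  bf <- signal::butter(order, 2 * cutoff / rate, type = "low")
  z <- exp(-1i * 2 * pi * f / rate)
  h <- sapply(z, function(zi)
    sum(bf$b * zi^(0:(length(bf$b) - 1L))) /
      sum(bf$a * zi^(0:(length(bf$a) - 1L))))
  Mod(h)^2
}
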