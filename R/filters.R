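# Second-order Butterworth biquads via the bilinear transform, and zero-phase
# forward-backward filtering. Hand-rolled because no DSP package is available;
# the design is verified against the analytic Butterworth magnitude response
# in the test suite.

butter2 <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  K <- tan(pi * fc / fs)
  s2 <- sqrt(2)
  norm <- 1 + s2 * K + K^2
  b <- if (type == "low") c(K^2, 2 * K^2, K^2) / norm
       else c(1, -2, 1) / norm
  a <- c(1, 2 * (K^2 - 1) / norm, (1 - s2 * K + K^2) / norm)
  list(b = b, a = a)
}

# Causal IIR filter using stats::filter for the fast inner loops.
iir_filter <- function(x, b, a) {
  np <- length(b) - 1L
  v <- stats::filter(c(rep(0, np), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[-seq_len(np)]
  as.numeric(stats::filter(v, -a[-1], method = "recursive"))
}

# Zero-phase (forward-backward) application with odd-reflection padding to
# suppress edge transients.
filtfilt2 <- function(x, b, a, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- min(n - 1L, 5000L)
  pad <- min(pad, n - 1L)
  z <- x
  if (pad > 0) {
    front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    z <- c(front, x, back)
  }
  z <- iir_filter(z, b, a)
  z <- rev(iir_filter(rev(z), b, a))
  if (pad > 0) z <- z[pad + seq_len(n)]
  z
}

#' Zero-phase second-order Butterworth band-pass
#'
#' Cascade of a second-order Butterworth high-pass and low-pass, each applied
#' forward and backward (zero phase, so event latencies are preserved at the
#' cost of squaring the magnitude response).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz (defaults 0.01 and 10).
#' @param pad Odd-reflection padding length in samples (default caps at
#'   min(n - 1, 5000)).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_butter <- function(x, fs, f_lo = 0.01, f_hi = 10, pad = NULL) {
  hp <- butter2(f_lo, fs, "high")
  lp <- butter2(f_hi, fs, "low")
  x <- filtfilt2(x, hp$b, hp$a, pad = pad)
  filtfilt2(x, lp$b, lp$a, pad = pad)
}
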