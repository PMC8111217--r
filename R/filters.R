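#' Zero-phase Butterworth bandpass filter
#'
#' Designs a Butterworth bandpass and applies it forward-backward
#' (`signal::filtfilt`) so the output is zero-phase.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band numeric length-2, band edges in Hz (low, high).
#' @param order filter order (the order of the underlying lowpass prototype).
#' @return filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, band, order = 4) {
  stopifnot(is.numeric(x), fs > 0, length(band) == 2)
  band <- sort(as.numeric(band))
  if (band[2] >= fs / 2)
    stop("bandpass_filter: upper band edge ", band[2],
         " Hz must be below Nyquist (", fs / 2, " Hz)")
  if (band[1] <= 0)
    stop("bandpass_filter: lower band edge must be > 0")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase 50 Hz notch: the magnitude response of the standard biquad
# notch (center f0, quality factor q) applied spectrally, so the filter is
# exactly zero-phase and free of the ring-down transients a high-Q IIR
# exhibits at segment edges.
notch_filter <- function(x, fs, f0 = 50, q = 30) {
  stopifnot(fs > 2 * f0, q > 0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha) / (1 + alpha)
  n <- length(x)
  w <- 2 * pi * (0:(n - 1)) / n
  ejw <- exp(-1i * w)
  H <- Mod((b[1] + b[2] * ejw + b[3] * ejw^2) /
             (a[1] + a[2] * ejw + a[3] * ejw^2))
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / n
}

#' Analytic signal via the FFT half-spectrum method
#'
#' Returns the complex analytic signal `x + i*H(x)` where `H` is the Hilbert
#' transform, computed by zeroing negative frequencies in the DFT.
#'
#' @param x real numeric signal.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n >= 2)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
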