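#' Canonical LFP frequency bands
#'
#' The five analysis bands used throughout the package, in Hz.
#'
#' @return named list of length-2 numeric vectors (low, high), half-open
#'   `[low, high)`.
#' @export
lfp_bands <- function() {
  list(
    "0.7-12"   = c(0.7, 12),
    "12-35"    = c(12, 35),
    "35-70"    = c(35, 70),
    "70-100"   = c(70, 100),
    "100-200"  = c(100, 200)
  )
}

# Internal: per-window, per-taper complex eigenspectra.
# x is split into non-overlapping windows of round(window_s*fs) samples
# (the trailing partial window is dropped), each tapered with the first
# n_tapers DPSS (time-bandwidth nw) and FFT'd at nfft = next power of two.
# Returns freqs (one-sided grid) and J: complex matrix nfreq x (nwin*ntapers).
.mt_spectra <- function(x, fs, window_s = 0.5, n_tapers = 5, nw = 3,
                        demean = TRUE) {
  nper <- round(window_s * fs)
  if (length(x) < nper)
    stop("multitaper: trace shorter than one analysis window (",
         nper, " samples)")
  nwin <- floor(length(x) / nper)
  if (demean) x <- x - mean(x)
  nfft <- 2^ceiling(log2(nper))
  tapers <- dpss_tapers(nper, nw, n_tapers)
  nfreq <- nfft %/% 2 + 1
  J <- matrix(0 + 0i, nfreq, nwin * n_tapers)
  col <- 1L
  for (w in seq_len(nwin)) {
    seg <- x[((w - 1) * nper + 1):(w * nper)]
    for (k in seq_len(n_tapers)) {
      padded <- numeric(nfft)
      padded[seq_len(nper)] <- seg * tapers[, k]
      J[, col] <- stats::fft(padded)[seq_len(nfreq)]
      col <- col + 1L
    }
  }
  list(freqs = seq(0, fs / 2, length.out = nfreq), J = J, nfft = nfft,
       n_windows = nwin, n_tapers = n_tapers)
}

#' Multitaper power spectral density
#'
#' Splits the trace into non-overlapping windows, tapers each with DPSS
#' (Slepian) sequences, and averages periodograms over tapers and windows.
#' One-sided density normalization: the integral of the PSD over frequency
#' approximates the signal variance (Parseval).
#'
#' @param trace an [lfp_trace] or numeric vector.
#' @param fs sampling rate (ignored when `trace` is an `lfp_trace`).
#' @param window_s analysis window length, seconds.
#' @param n_tapers number of DPSS tapers.
#' @param nw time-bandwidth product.
#' @return object of class `psd_result`: `freqs` (Hz), `power`
#'   (units^2/Hz), `params`.
#' @export
multitaper_psd <- function(trace, fs = NULL, window_s = 0.5, n_tapers = 5,
                           nw = 3) {
  if (inherits(trace, "lfp_trace")) {
    x <- trace$samples
    fs <- trace$fs
  } else {
    x <- as.numeric(trace)
    if (is.null(fs)) stop("multitaper_psd: fs required for a bare vector")
  }
  mt <- .mt_spectra(x, fs, window_s, n_tapers, nw)
  pxx <- rowMeans(Mod(mt$J)^2) / fs
  # one-sided: double everything except DC and Nyquist
  n <- length(pxx)
  pxx[2:(n - 1)] <- 2 * pxx[2:(n - 1)]
  structure(
    list(freqs = mt$freqs, power = pxx,
         params = list(n_tapers = n_tapers, time_bandwidth = nw,
                       window_s = window_s, fs = fs,
                       n_windows = mt$n_windows)),
    class = "psd_result"
  )
}

#' @export
print.psd_result <- function(x, ...) {
  cat(sprintf(
    "<psd_result: %d freqs 0-%g Hz, %d tapers, NW=%g, %g s windows x %d>\n",
    length(x$freqs), max(x$freqs), x$params$n_tapers, x$params$time_bandwidth,
    x$params$window_s, x$params$n_windows))
  invisible(x)
}

#' Relative band power
#'
#' Fraction of spectral power in each band, relative to the total power over
#' the union of the given bands (0.7-200 Hz for the default bands). Band
#' edges are half-open `[low, high)` on the discrete frequency grid.
#'
#' @param psd a `psd_result` from [multitaper_psd].
#' @param bands named list of band edges; defaults to [lfp_bands()].
#' @return object of class `band_power_result`: `bands`, `fractions`
#'   (named, in `[0,1]`, summing to 1 up to rounding), `band_power`,
#'   `total_power`.
#' @export
relative_band_power <- function(psd, bands = lfp_bands()) {
  stopifnot(inherits(psd, "psd_result"), length(bands) >= 1)
  fmax <- max(psd$freqs)
  df <- psd$freqs[2] - psd$freqs[1]
  sel <- lapply(bands, function(b) {
    if (b[1] < 0 || b[2] > fmax + df / 2)
      stop("relative_band_power: band outside the spectral support")
    idx <- which(psd$freqs >= b[1] & psd$freqs < b[2])
    if (length(idx) == 0)
      stop("relative_band_power: band [", b[1], ",", b[2],
           ") empty after discretization (df = ", df, " Hz)")
    idx
  })
  band_power <- vapply(sel, function(idx) sum(psd$power[idx]) * df, 0.0)
  total <- sum(psd$power[sort(unique(unlist(sel)))]) * df
  structure(
    list(bands = bands, fractions = band_power / total,
         band_power = band_power, total_power = total),
    class = "band_power_result"
  )
}

#' @export
print.band_power_result <- function(x, ...) {
  cat("<band_power_result>\n")
  print(round(x$fractions, 4))
  invisible(x)
}

#' Short-time Fourier transform spectrogram
#'
#' Hann-tapered STFT power, stored linear (log scaling is a display choice).
#'
#' @param trace an [lfp_trace] or numeric vector.
#' @param fs sampling rate (ignored for an `lfp_trace`).
#' @param window_s window length, seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return object of class `spectrogram_result`: `times` (window centers,
#'   s), `freqs` (Hz), `power` (time x frequency matrix, units^2/Hz).
#' @export
lfp_spectrogram <- function(trace, fs = NULL, window_s = 0.5, overlap = 0.5) {
  if (inherits(trace, "lfp_trace")) {
    x <- trace$samples
    fs <- trace$fs
    t0 <- trace$t0
  } else {
    x <- as.numeric(trace)
    if (is.null(fs)) stop("lfp_spectrogram: fs required for a bare vector")
    t0 <- 0
  }
  if (overlap < 0 || overlap >= 1)
    stop("lfp_spectrogram: overlap must be in [0, 1)")
  nper <- round(window_s * fs)
  if (length(x) < nper) stop("lfp_spectrogram: trace shorter than one window")
  hop <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1)) # Hann
  nfft <- 2^ceiling(log2(nper))
  nfreq <- nfft %/% 2 + 1
  scale <- 1 / (fs * sum(h^2))
  P <- matrix(0, length(starts), nfreq)
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nper - 1)]
    seg <- (seg - mean(seg)) * h
    padded <- numeric(nfft)
    padded[seq_len(nper)] <- seg
    sp <- Mod(stats::fft(padded)[seq_len(nfreq)])^2 * scale
    sp[2:(nfreq - 1)] <- 2 * sp[2:(nfreq - 1)]
    P[i, ] <- sp
  }
  structure(
    list(times = t0 + (starts - 1 + nper / 2) / fs,
         freqs = seq(0, fs / 2, length.out = nfreq),
         power = P,
         params = list(window_s = window_s, overlap = overlap, fs = fs)),
    class = "spectrogram_result"
  )
}
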