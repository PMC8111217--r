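#' LFP trace container
#'
#' A light S3 container for one local field potential channel.
#'
#' @param samples numeric vector of voltages (arbitrary units).
#' @param fs sampling rate, Hz.
#' @param t0 time of the first sample, seconds.
#' @param channel_id channel identifier.
#' @return an object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs = 1000, t0 = 0, channel_id = "lfp1") {
  stopifnot(is.numeric(samples), length(samples) >= 1, fs > 0,
            all(is.finite(samples)))
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         t0 = as.numeric(t0), channel_id = as.character(channel_id)),
    class = "lfp_trace"
  )
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace %s: %d samples @ %g Hz, %.1f s>\n",
              x$channel_id, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Time axis of an LFP trace
#' @param trace an `lfp_trace`.
#' @return numeric vector of sample times in seconds.
#' @export
lfp_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) / trace$fs
}

#' Standard LFP preprocessing
#'
#' Zero-phase 0.5-200 Hz Butterworth bandpass (4th order, forward-backward)
#' followed by a zero-phase 50 Hz notch (Q = 30) to suppress line artifacts.
#' Length is preserved.
#'
#' @param trace an [lfp_trace].
#' @param band passband edges in Hz.
#' @param notch_hz line frequency to notch out; `NA` disables the notch.
#' @param q notch quality factor.
#' @return the preprocessed `lfp_trace`.
#' @export
lfp_preprocess <- function(trace, band = c(0.5, 200), notch_hz = 50, q = 30) {
  stopifnot(inherits(trace, "lfp_trace"))
  if (trace$fs <= 400)
    stop("lfp_preprocess: sampling rate must exceed 400 Hz")
  if (band[2] >= trace$fs / 2)
    stop("lfp_preprocess: band edge at or above Nyquist")
  y <- bandpass_filter(trace$samples, trace$fs, band, order = 4)
  if (!is.na(notch_hz)) y <- notch_filter(y, trace$fs, notch_hz, q)
  trace$samples <- y
  trace
}
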