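#' Instantaneous phase of a band-limited LFP
#'
#' Bandpass-filters the trace with a 3rd-order Butterworth (zero-phase,
#' forward-backward) and takes the analytic-signal angle, mapped to degrees
#' in `[0, 360)`. With this construction, local maxima (peaks) of the
#' band-limited oscillation sit at 0 degrees and troughs at 180 degrees.
#'
#' @param lfp an [lfp_trace] or numeric vector.
#' @param band length-2 numeric band edges, Hz.
#' @param fs sampling rate (ignored for an `lfp_trace`).
#' @param order Butterworth order.
#' @return numeric vector of phases in degrees, one per sample.
#' @export
instantaneous_phase <- function(lfp, band, fs = NULL, order = 3) {
  if (inherits(lfp, "lfp_trace")) {
    x <- lfp$samples
    fs <- lfp$fs
  } else {
    x <- as.numeric(lfp)
    if (is.null(fs)) stop("instantaneous_phase: fs required for a bare vector")
  }
  if (band[2] >= fs / 2) stop("instantaneous_phase: band edge at or above Nyquist")
  if (length(x) < 3 * fs / band[1])
    stop("instantaneous_phase: trace shorter than 3 cycles of the band low edge")
  filt <- bandpass_filter(x, fs, band, order = order)
  (Arg(analytic_signal(filt)) * 180 / pi) %% 360
}

#' Per-spike phase lookup
#'
#' Assigns each spike the phase of the nearest LFP sample. Spikes outside
#' the phase-series support are dropped (their count is reported).
#'
#' @param train a [spike_train] (or numeric spike times, seconds).
#' @param phase_deg phase series from [instantaneous_phase], degrees.
#' @param fs sampling rate of the phase series, Hz.
#' @param t0 time of the first phase sample, seconds.
#' @return numeric vector of per-spike phases (degrees) with attribute
#'   `n_dropped`.
#' @export
spike_phases <- function(train, phase_deg, fs = 1000, t0 = 0) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  n <- length(phase_deg)
  ok <- times >= t0 & times < t0 + n / fs
  if (any(!ok))
    warning(sum(!ok), " spikes outside the phase-series support were dropped")
  idx <- pmin(pmax(round((times[ok] - t0) * fs) + 1, 1L), n)
  structure(phase_deg[idx], n_dropped = sum(!ok))
}

# Internal: multitaper coherence between two equally sampled signals.
# C(f) = |mean(Jx * Conj(Jy))| / sqrt(mean|Jx|^2 * mean|Jy|^2), means over
# windows and tapers.
.mt_coherence <- function(x, y, fs, window_s = 0.5, n_tapers = 5, nw = 3) {
  stopifnot(length(x) == length(y))
  mx <- .mt_spectra(x, fs, window_s, n_tapers, nw)
  my <- .mt_spectra(y, fs, window_s, n_tapers, nw)
  sxy <- rowMeans(mx$J * Conj(my$J))
  sxx <- rowMeans(Mod(mx$J)^2)
  syy <- rowMeans(Mod(my$J)^2)
  coh <- Mod(sxy) / sqrt(sxx * syy)
  coh[!is.finite(coh)] <- 0
  list(freqs = mx$freqs, coherence = coh, n_windows = mx$n_windows)
}

#' Multitaper coherence between two continuous signals
#'
#' Degenerate continuous-continuous mode of the spike-field machinery;
#' identical inputs give coherence 1 at every frequency.
#'
#' @param x,y numeric signals of equal length.
#' @param fs sampling rate, Hz.
#' @param window_s analysis window, seconds.
#' @param n_tapers number of DPSS tapers.
#' @param nw time-bandwidth product.
#' @return list: `freqs`, `coherence` in `[0, 1]`.
#' @export
multitaper_coherence <- function(x, y, fs, window_s = 0.5, n_tapers = 5,
                                 nw = 3) {
  .mt_coherence(as.numeric(x), as.numeric(y), fs, window_s, n_tapers, nw)
}

#' Spike-field coherence
#'
#' Multitaper coherence between a spike train (embedded as mean-centered
#' 1 ms binned counts at the LFP sampling rate) and the LFP: 0.5 s windows,
#' 5 DPSS tapers, NW = 3, cross- and auto-spectra averaged over windows and
#' tapers. Values lie in `[0, 1]` by construction.
#'
#' @param train a [spike_train].
#' @param lfp an [lfp_trace].
#' @param bands named list of bands for band-mean coherence; defaults to
#'   the three coupling-analysis bands.
#' @param window_s analysis window, seconds.
#' @param n_tapers number of DPSS tapers.
#' @param nw time-bandwidth product.
#' @param min_spikes admissibility criterion (>= 40 spikes).
#' @param min_windows minimum number of analysis windows.
#' @return object of class `coherence_result`: `freqs`, `coherence`,
#'   `band_means` (unweighted mean of C(f) inside each band), `n_spikes`,
#'   `params`.
#' @export
spike_field_coherence <- function(train, lfp,
                                  bands = lfp_bands()[c("0.7-12", "12-35", "35-70")],
                                  window_s = 0.5, n_tapers = 5, nw = 3,
                                  min_spikes = 40, min_windows = 10) {
  stopifnot(inherits(train, "spike_train"), inherits(lfp, "lfp_trace"))
  fs <- lfp$fs
  n <- length(lfp$samples)
  if (floor(n / round(window_s * fs)) < min_windows)
    stop("spike_field_coherence: fewer than ", min_windows,
         " analysis windows of overlap")
  t_lfp <- c(lfp$t0, lfp$t0 + n / fs)
  in_support <- train$times >= t_lfp[1] & train$times < t_lfp[2]
  n_spk <- sum(in_support)
  if (n_spk < min_spikes)
    stop("spike_field_coherence: ", n_spk, " spikes < admissibility minimum of ",
         min_spikes)
  binned <- tabulate(floor((train$times[in_support] - lfp$t0) * fs) + 1,
                     nbins = n)
  binned <- binned - mean(binned)
  co <- .mt_coherence(binned, lfp$samples, fs, window_s, n_tapers, nw)
  band_means <- vapply(bands, function(b) {
    idx <- which(co$freqs >= b[1] & co$freqs < b[2])
    mean(co$coherence[idx])
  }, 0.0)
  structure(
    list(freqs = co$freqs, coherence = co$coherence, band_means = band_means,
         n_spikes = n_spk,
         params = list(window_s = window_s, n_tapers = n_tapers, nw = nw,
                       n_windows = co$n_windows)),
    class = "coherence_result"
  )
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result: %d spikes, %d windows>\n",
              x$n_spikes, x$params$n_windows))
  if (length(x$band_means)) print(round(x$band_means, 3))
  invisible(x)
}

#' Spike-LFP phase locking for one unit and band
#'
#' Convenience wrapper: band-limited instantaneous phase, per-spike phase
#' lookup, then circular summary with the >= 40-spike criterion.
#'
#' @param train a [spike_train].
#' @param lfp an [lfp_trace].
#' @param band length-2 numeric band, Hz.
#' @param intervals optional 2-column matrix of (start, end) s; only spikes
#'   inside these intervals are used (e.g. movement epochs).
#' @param min_spikes admissibility threshold.
#' @param alpha Rayleigh significance level.
#' @return a [phase_lock_summary] result.
#' @export
spike_lfp_phase_locking <- function(train, lfp, band, intervals = NULL,
                                    min_spikes = 40, alpha = 0.05) {
  ph <- instantaneous_phase(lfp, band)
  times <- train$times
  if (!is.null(intervals)) {
    times <- restrict_train(train, intervals)$times
  }
  ang <- spike_phases(times, ph, fs = lfp$fs, t0 = lfp$t0)
  phase_lock_summary(ang, band = band, min_spikes = min_spikes, alpha = alpha)
}
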