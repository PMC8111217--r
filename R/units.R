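#' Waveform set container
#'
#' Spike waveform snippets for one unit, one row per spike, sampled at
#' `fs` (40 kHz in the standard acquisition setup).
#'
#' @param snippets numeric matrix, n_spikes x n_samples.
#' @param fs sampling rate in Hz.
#' @param unit_id unit identifier.
#' @param alignment_index sample index (1-based) of the threshold crossing
#'   within each snippet.
#' @return object of class `waveform_set`.
#' @export
waveform_set <- function(snippets, fs = 40000, unit_id = "u1",
                         alignment_index = NULL) {
  snippets <- as.matrix(snippets)
  stopifnot(ncol(snippets) >= 32, all(is.finite(snippets)), fs > 0)
  structure(
    list(unit_id = as.character(unit_id), snippets = snippets, fs = fs,
         alignment_index = alignment_index),
    class = "waveform_set"
  )
}

#' @export
print.waveform_set <- function(x, ...) {
  cat(sprintf("<waveform_set %s: %d spikes x %d samples @ %g Hz>\n",
              x$unit_id, nrow(x$snippets), ncol(x$snippets), x$fs))
  invisible(x)
}

#' Threshold-based spike detection on a broadband trace
#'
#' Detects negative-going threshold crossings and cuts a snippet window of
#' \[-0.4, +1.2\] ms around each crossing. Crossings within `dead_time_ms`
#' of an accepted detection are suppressed, as are crossings too close to
#' the trace edges for a full snippet.
#'
#' @param x numeric broadband trace (typically 40 kHz).
#' @param fs sampling rate, Hz.
#' @param threshold detection threshold (volts, negative for negative-going
#'   spikes).
#' @param dead_time_ms minimum separation between accepted detections, ms.
#' @param window_ms snippet window around the crossing, ms (pre, post).
#' @return list with `waveforms` (a [waveform_set], 0 rows if no
#'   detections) and `times` (crossing times in seconds, ascending).
#' @export
detect_spikes <- function(x, fs, threshold, dead_time_ms = 1,
                          window_ms = c(-0.4, 1.2)) {
  stopifnot(is.numeric(x), fs > 0, is.finite(threshold), dead_time_ms >= 0)
  pre <- round(-window_ms[1] * fs / 1000)
  post <- round(window_ms[2] * fs / 1000)
  nsamp <- pre + post + 1
  if (length(x) < nsamp)
    stop("detect_spikes: trace shorter than one snippet window")
  crossings <- which(x[-1] < threshold & x[-length(x)] >= threshold) + 1L
  crossings <- crossings[crossings > pre & crossings + post <= length(x)]
  dead <- max(1L, round(dead_time_ms * fs / 1000))
  keep <- integer(0)
  last <- -Inf
  for (i in crossings) {
    if (i - last >= dead) {
      keep <- c(keep, i)
      last <- i
    }
  }
  snips <- matrix(0, length(keep), nsamp)
  for (j in seq_along(keep)) {
    snips[j, ] <- x[(keep[j] - pre):(keep[j] + post)]
  }
  list(
    waveforms = waveform_set(
      if (length(keep)) snips else matrix(0, 0, nsamp),
      fs = fs, unit_id = "detected", alignment_index = pre + 1),
    times = (keep - 1) / fs
  )
}

#' Trough-to-peak duration of a spike waveform
#'
#' Duration from the global trough (first negative deflection) to the
#' maximum after the trough (the second, positive deflection), in ms.
#' A snippet with no positive-going deflection after its trough is
#' non-canonical and raises a condition of class `non_canonical_waveform`.
#'
#' @param snippet numeric vector, one waveform.
#' @param fs sampling rate, Hz.
#' @return duration in ms (> 0).
#' @export
trough_to_peak <- function(snippet, fs) {
  stopifnot(is.numeric(snippet), all(is.finite(snippet)), fs > 0)
  i_trough <- which.min(snippet)
  if (i_trough >= length(snippet))
    stop(.non_canonical("trough at the last sample; no post-trough peak"))
  post <- snippet[(i_trough + 1):length(snippet)]
  i_peak <- i_trough + which.max(post)
  # no rise anywhere from the trough onward -> no identifiable second
  # (positive) deflection
  if (all(diff(snippet[i_trough:length(snippet)]) <= 0))
    stop(.non_canonical("no positive deflection after the trough"))
  (i_peak - i_trough) / fs * 1000
}

.non_canonical <- function(msg) {
  structure(
    class = c("non_canonical_waveform", "error", "condition"),
    list(message = paste0("non-canonical waveform: ", msg), call = NULL)
  )
}

#' Classify a unit as broad-spiking (BS) or narrow-spiking (NS)
#'
#' Units with trough-to-peak duration >= 0.32 ms (the midpoint between the
#' canonical BS and NS class means of 0.42 and 0.22 ms) are labeled `BS`
#' (putative pyramidal), shorter ones `NS` (putative interneuron). The
#' firing rate is recorded for diagnostics but is not a hard criterion.
#'
#' @param duration_ms trough-to-peak duration, ms.
#' @param mean_rate_hz mean firing rate, spikes/s (optional, recorded only).
#' @param boundary_ms class boundary, ms; ties go to `BS`.
#' @return `"BS"` or `"NS"`.
#' @export
classify_unit <- function(duration_ms, mean_rate_hz = NA_real_,
                          boundary_ms = 0.32) {
  stopifnot(duration_ms > 0)
  if (duration_ms >= boundary_ms) "BS" else "NS"
}

#' Refractory-period criterion
#'
#' A unit passes when fewer than `max_violation_fraction` of its
#' interspike intervals fall below `min_isi_ms`. Trains with fewer than two
#' spikes pass by convention (nothing to violate) and are flagged.
#'
#' @param spike_times ascending spike times, seconds.
#' @param min_isi_ms refractory period, ms.
#' @param max_violation_fraction maximum tolerated violating fraction.
#' @return logical; attribute `low_count` is `TRUE` when < 2 spikes.
#' @export
refractory_ok <- function(spike_times, min_isi_ms = 2,
                          max_violation_fraction = 0.01) {
  stopifnot(!is.unsorted(spike_times))
  if (length(spike_times) < 2)
    return(structure(TRUE, low_count = TRUE))
  isi_ms <- diff(spike_times) * 1000
  structure(mean(isi_ms < min_isi_ms) < max_violation_fraction,
            low_count = FALSE)
}

#' Classify all units of a session
#'
#' Measures the trough-to-peak duration on the mean waveform of each unit,
#' applies the refractory criterion to its spike train, and assigns the
#' BS/NS class. Units with non-canonical mean waveforms are labeled
#' `unclassified`.
#'
#' @param waveforms list of [waveform_set]s.
#' @param trains list of [spike_train]s (same order/unit ids).
#' @return data.frame: unit_id, trough_to_peak_ms, mean_rate_hz,
#'   class_label, refractory_ok.
#' @export
classify_units <- function(waveforms, trains) {
  stopifnot(length(waveforms) == length(trains))
  rows <- lapply(seq_along(waveforms), function(i) {
    wf <- waveforms[[i]]
    tr <- trains[[i]]
    rate <- mean_rate(tr)
    mean_wf <- colMeans(wf$snippets)
    dur <- tryCatch(trough_to_peak(mean_wf, wf$fs),
                    non_canonical_waveform = function(e) NA_real_)
    data.frame(
      unit_id = wf$unit_id,
      trough_to_peak_ms = dur,
      mean_rate_hz = rate,
      class_label = if (is.na(dur)) "unclassified" else classify_unit(dur, rate),
      refractory_ok = as.logical(refractory_ok(tr$times)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' PCA diagnostic of waveform shape
#'
#' Projects all snippets of several units onto the first principal
#' components of the pooled waveform matrix; a visualization aid only,
#' classification never depends on it.
#'
#' @param waveforms list of [waveform_set]s.
#' @param n_components number of PCs to keep.
#' @return data.frame of scores with a `unit_id` column.
#' @export
waveform_pca <- function(waveforms, n_components = 3) {
  mats <- lapply(waveforms, function(w) w$snippets)
  ids <- rep(vapply(waveforms, function(w) w$unit_id, ""),
             vapply(mats, nrow, 0L))
  pooled <- do.call(rbind, mats)
  pc <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
  scores <- as.data.frame(pc$x[, seq_len(min(n_components, ncol(pc$x))),
                               drop = FALSE])
  scores$unit_id <- ids
  scores
}
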