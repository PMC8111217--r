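#' Spike train container
#'
#' @param times strictly ascending spike times, seconds.
#' @param t_start,t_stop recording support, seconds.
#' @param unit_id unit identifier.
#' @param class_label optional class label (`BS`, `NS`, `unclassified`).
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, t_start = 0,
                        t_stop = if (length(times)) max(times) else t_start,
                        unit_id = "u1", class_label = NA_character_) {
  times <- as.numeric(times)
  if (length(times)) {
    if (is.unsorted(times, strictly = TRUE))
      stop("spike_train: times must be strictly ascending (no duplicates)")
    if (times[1] < t_start || times[length(times)] > t_stop)
      stop("spike_train: times outside [t_start, t_stop]")
  }
  stopifnot(t_stop >= t_start)
  structure(
    list(unit_id = as.character(unit_id), times = times,
         t_start = as.numeric(t_start), t_stop = as.numeric(t_stop),
         class_label = class_label),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train %s%s: %d spikes on [%g, %g] s>\n",
              x$unit_id,
              if (is.na(x$class_label)) "" else paste0(" (", x$class_label, ")"),
              length(x$times), x$t_start, x$t_stop))
  invisible(x)
}

#' Restrict a spike train to a set of intervals
#'
#' Keeps spikes falling in any of the (non-overlapping) intervals; the
#' restricted train's support length is the summed interval length, used by
#' rate computations over behavioral states.
#'
#' @param train a [spike_train].
#' @param intervals 2-column matrix or data.frame of (start, end) seconds.
#' @return list: `times` (kept spikes), `total_time` (summed length, s).
#' @export
restrict_train <- function(train, intervals) {
  iv <- as.matrix(intervals)[, 1:2, drop = FALSE]
  stopifnot(all(iv[, 2] > iv[, 1]))
  keep <- rep(FALSE, length(train$times))
  for (r in seq_len(nrow(iv))) {
    keep <- keep | (train$times >= iv[r, 1] & train$times < iv[r, 2])
  }
  list(times = train$times[keep], total_time = sum(iv[, 2] - iv[, 1]))
}

#' Mean firing rate
#'
#' Total spike count in the interval divided by the interval length.
#'
#' @param train a [spike_train].
#' @param interval length-2 numeric (start, end) seconds; defaults to the
#'   train's full support.
#' @return rate in spikes/s.
#' @export
mean_rate <- function(train, interval = c(train$t_start, train$t_stop)) {
  len <- interval[2] - interval[1]
  if (len <= 0) stop("mean_rate: interval length must be > 0")
  sum(train$times >= interval[1] & train$times < interval[2]) / len
}

# ISIs of a train; errors below a minimum count.
.isis <- function(train, min_isi = 1) {
  if (length(train$times) < min_isi + 1)
    stop("spike train has fewer than ", min_isi + 1,
         " spikes; ISI statistic undefined")
  diff(train$times)
}

#' Coefficient of variation of the interspike intervals
#'
#' Population standard deviation of the ISIs divided by their mean.
#' Exponential (Poisson) ISIs give CV near one; more regular trains fall
#' below one.
#'
#' @param train a [spike_train] with at least 3 spikes.
#' @return unitless CV >= 0.
#' @export
isi_cv <- function(train) {
  isi <- .isis(train, min_isi = 2)
  m <- mean(isi)
  sqrt(mean((isi - m)^2)) / m
}

#' Mode of the interspike-interval histogram
#'
#' Center of the most populated ISI-histogram bin (default 5 ms bins on
#' \[0, 1\] s); ties resolved to the smallest bin center.
#'
#' @param train a [spike_train] with at least 2 ISIs.
#' @param bin_width_s histogram bin width, seconds.
#' @param range_s histogram range, seconds.
#' @return mode in seconds (a bin center).
#' @export
isi_mode <- function(train, bin_width_s = 0.005, range_s = c(0, 1)) {
  isi <- .isis(train, min_isi = 2)
  edges <- seq(range_s[1], range_s[2], by = bin_width_s)
  isi <- isi[isi >= range_s[1] & isi < range_s[2]]
  if (length(isi) == 0)
    stop("isi_mode: all ISIs outside the histogram range")
  counts <- tabulate(.isi_bin(isi, range_s[1], bin_width_s),
                     nbins = length(edges) - 1)
  edges[which.max(counts)] + bin_width_s / 2
}

# bin index with a small relative epsilon so ISIs an ulp below a bin edge
# (from accumulated timestamp rounding) land in the edge's bin
.isi_bin <- function(isi, lo, bw) {
  floor((isi - lo) / bw + 1e-9) + 1L
}

#' ISI asymmetry index
#'
#' Ratio of the ISI-histogram mode to the mean ISI. Values near one
#' indicate regular firing; values well below one an asymmetric (irregular
#' or bursty) ISI distribution.
#'
#' @inheritParams isi_mode
#' @return unitless index >= 0.
#' @export
asymmetry_index <- function(train, bin_width_s = 0.005, range_s = c(0, 1)) {
  isi <- .isis(train, min_isi = 2)
  isi_mode(train, bin_width_s, range_s) / mean(isi)
}

#' All ISI pattern statistics for one train
#'
#' @inheritParams isi_mode
#' @param interval support interval for the rate, seconds.
#' @return object of class `isi_stats`: n_spikes, mean_rate, cv, mode_s,
#'   asymmetry_index, isi_histogram (edges, counts).
#' @export
isi_stats <- function(train, interval = c(train$t_start, train$t_stop),
                      bin_width_s = 0.005, range_s = c(0, 1)) {
  edges <- seq(range_s[1], range_s[2], by = bin_width_s)
  n <- length(train$times)
  isi <- if (n >= 2) diff(train$times) else numeric(0)
  counts <- tabulate(
    .isi_bin(isi[isi >= range_s[1] & isi < range_s[2]], range_s[1],
             bin_width_s),
    nbins = length(edges) - 1)
  structure(
    list(
      n_spikes = n,
      mean_rate = mean_rate(train, interval),
      cv = if (n >= 3) isi_cv(train) else NA_real_,
      mode_s = if (n >= 3) isi_mode(train, bin_width_s, range_s) else NA_real_,
      asymmetry_index = if (n >= 3)
        asymmetry_index(train, bin_width_s, range_s) else NA_real_,
      isi_histogram = list(edges = edges, counts = counts)
    ),
    class = "isi_stats"
  )
}
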