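#' @export
plot.peth_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  # raster
  graphics::plot(NA, xlim = x$window, ylim = c(0, nrow(x$counts) + 1),
                 xlab = "", ylab = "trial", ...)
  for (t in seq_len(nrow(x$counts))) {
    b <- which(x$counts[t, ] > 0)
    if (length(b))
      graphics::points(x$bin_centers[b], rep(t, length(b)), pch = "|",
                       cex = 0.4)
  }
  graphics::abline(v = 0, lty = 2)
  graphics::plot(x$bin_centers, x$rate, type = "l",
                 xlab = "time from event (s)", ylab = "rate (spikes/s)")
  graphics::abline(v = 0, lty = 2)
  graphics::abline(h = x$baseline_rate, col = "grey50", lty = 3)
  invisible(x)
}

#' @export
plot.psd_result <- function(x, log = "y", xlim = c(0, 200), ...) {
  keep <- x$freqs >= xlim[1] & x$freqs <= xlim[2] & x$power > 0
  graphics::plot(x$freqs[keep], x$power[keep], type = "l", log = log,
                 xlab = "frequency (Hz)", ylab = "PSD (units^2/Hz)", ...)
  invisible(x)
}

#' @export
plot.spectrogram_result <- function(x, flim = c(0, 100), ...) {
  keep <- x$freqs >= flim[1] & x$freqs <= flim[2]
  graphics::image(x$times, x$freqs[keep], log10(x$power[, keep] + 1e-12),
                  xlab = "time (s)", ylab = "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Rose-style circular phase histogram (diagnostic)
#'
#' @param x a `phase_lock_result`.
#' @param n_bins number of angular bins.
#' @param ... passed to plot.
#' @export
plot.phase_lock_result <- function(x, n_bins = 18, ...) {
  th <- x$phases_deg * pi / 180
  edges <- seq(0, 2 * pi, length.out = n_bins + 1)
  counts <- tabulate(findInterval(th %% (2 * pi), edges,
                                  rightmost.closed = TRUE), nbins = n_bins)
  r <- counts / max(counts, 1)
  graphics::plot(NA, xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", ...)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "grey70")
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  graphics::segments(0, 0, r * cos(mid), r * sin(mid), col = "grey40")
  if (is.finite(x$mean_angle_deg)) {
    mu <- x$mean_angle_deg * pi / 180
    graphics::arrows(0, 0, x$vector_length * cos(mu),
                     x$vector_length * sin(mu), col = "blue", lwd = 2,
                     length = 0.08)
  }
  invisible(x)
}
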