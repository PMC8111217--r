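#' Circular mean angle and mean resultant (vector) length
#'
#' @param angles_deg angles in degrees.
#' @return list: `mean_angle_deg` in `[0, 360)` (`NA` when the resultant is
#'   numerically zero), `vector_length` R in `[0, 1]`, `n`.
#' @export
circular_summary <- function(angles_deg) {
  n <- length(angles_deg)
  if (n == 0)
    return(list(mean_angle_deg = NA_real_, vector_length = NA_real_, n = 0L))
  th <- angles_deg * pi / 180
  z <- mean(complex(real = cos(th), imaginary = sin(th)))
  r <- Mod(z)
  mu <- if (r < 1e-12) NA_real_ else (Arg(z) * 180 / pi) %% 360
  list(mean_angle_deg = mu, vector_length = r, n = as.integer(n))
}

#' Rayleigh test of circular uniformity
#'
#' Tests spike-phase angles against the uniform circular distribution.
#' Uses the refined exponential approximation
#' `p = exp(sqrt(1 + 4n + 4(n^2 - (nR)^2)) - (1 + 2n))`, where `R` is the
#' mean resultant length; small p indicates phase-locked firing.
#'
#' @param angles_deg angles in degrees (n >= 1).
#' @return list: `p` in `(0, 1]`, `z` (Rayleigh statistic `n*R^2`), `r`
#'   (mean resultant length), `n`.
#' @export
rayleigh_test <- function(angles_deg) {
  n <- length(angles_deg)
  stopifnot(n >= 1)
  r <- circular_summary(angles_deg)$vector_length
  rn <- n * r
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - rn^2)) - (1 + 2 * n))
  list(p = min(1, p), z = n * r^2, r = r, n = as.integer(n))
}

#' Phase-locking summary for one unit and band
#'
#' Circular statistics over per-spike phases, with the >= 40-spike
#' admissibility criterion: the circular mean is only trusted (and the
#' locked verdict only issued) for units contributing at least 40 spikes.
#'
#' @param angles_deg per-spike phase angles, degrees.
#' @param band optional length-2 numeric, the LFP band the phases came from.
#' @param min_spikes admissibility threshold.
#' @param alpha Rayleigh significance level.
#' @return object of class `phase_lock_result`: `band`, `phases_deg`,
#'   `mean_angle_deg`, `vector_length`, `rayleigh_p`, `n_spikes`,
#'   `admissible`, `locked`.
#' @export
phase_lock_summary <- function(angles_deg, band = NULL, min_spikes = 40,
                               alpha = 0.05) {
  angles_deg <- as.numeric(angles_deg) %% 360
  cs <- circular_summary(angles_deg)
  n <- cs$n
  ray <- if (n >= 1) rayleigh_test(angles_deg) else list(p = NA_real_)
  admissible <- n >= min_spikes
  structure(
    list(band = band,
         phases_deg = angles_deg,
         mean_angle_deg = cs$mean_angle_deg,
         vector_length = cs$vector_length,
         rayleigh_p = ray$p,
         n_spikes = n,
         admissible = admissible,
         locked = admissible && is.finite(ray$p) && ray$p < alpha),
    class = "phase_lock_result"
  )
}

#' @export
print.phase_lock_result <- function(x, ...) {
  cat(sprintf(
    "<phase_lock_result: n=%d%s, mean angle %.1f deg, R=%.3f, Rayleigh p=%.3g%s>\n",
    x$n_spikes, if (x$admissible) "" else " (inadmissible, <40 spikes)",
    x$mean_angle_deg, x$vector_length, x$rayleigh_p,
    if (isTRUE(x$locked)) ", locked" else ""))
  invisible(x)
}
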