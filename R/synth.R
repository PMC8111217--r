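#' Unit specification for the synthetic generator
#'
#' Ground-truth parameters of one simulated unit: class label, baseline
#' rate, waveform trough-to-peak duration, von Mises phase coupling to an
#' LFP band (concentration `kappa`, preferred phase `mu`), and a
#' multiplicative movement gain applied inside movement windows.
#'
#' @param class_label `"BS"` or `"NS"`.
#' @param base_rate baseline firing rate, spikes/s (>= 0).
#' @param trough_to_peak_ms waveform trough-to-peak duration, ms (> 0).
#' @param coupling_band length-2 numeric band (Hz) or `NULL` for no coupling.
#' @param kappa von Mises concentration (>= 0; 0 means no phase preference).
#' @param preferred_phase_deg preferred phase, degrees in `[0, 360)`.
#' @param movement_gain rate multiplier inside movement windows (>= 0).
#' @param waveform_noise_sd waveform noise SD as a fraction of the trough
#'   amplitude.
#' @return object of class `unit_spec`.
#' @export
unit_spec <- function(class_label = c("BS", "NS"), base_rate = 5,
                      trough_to_peak_ms = 0.42, coupling_band = NULL,
                      kappa = 0, preferred_phase_deg = 0,
                      movement_gain = 1, waveform_noise_sd = 0.05) {
  class_label <- match.arg(class_label)
  stopifnot(base_rate >= 0, kappa >= 0, trough_to_peak_ms > 0,
            movement_gain >= 0, waveform_noise_sd >= 0)
  structure(
    list(class_label = class_label, base_rate = base_rate,
         trough_to_peak_ms = trough_to_peak_ms,
         coupling_band = coupling_band, kappa = kappa,
         preferred_phase_deg = preferred_phase_deg %% 360,
         movement_gain = movement_gain,
         waveform_noise_sd = waveform_noise_sd),
    class = "unit_spec"
  )
}

#' Synthetic session configuration
#'
#' @param seed integer RNG seed; everything downstream is deterministic
#'   given the config (including the seed).
#' @param duration_s session length, seconds.
#' @param lfp_fs LFP sampling rate, Hz.
#' @param wf_fs waveform sampling rate, Hz.
#' @param band_fractions named numeric vector, target fraction of total LFP
#'   power per band (names matching [lfp_bands()]); each in `[0, 1]`,
#'   summing to at most 1. Any residual is carried by a broadband 1/f
#'   background.
#' @param one_over_f_exponent spectral tilt alpha of the 1/f^alpha envelope.
#' @param units list of [unit_spec]s.
#' @param events list: `iei_range` (uniform inter-event interval bounds, s),
#'   `move_duration_mean`, `move_duration_sd` (movement-window length, s).
#' @param condition_label `"control"` or `"lesioned"`.
#' @param component_mode `"noise"` (Hann-envelope band-limited noise;
#'   default) or `"tone"` (one sinusoid per band at its geometric center,
#'   for analytic tests).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1, duration_s = 300, lfp_fs = 1000,
                         wf_fs = 40000,
                         band_fractions = c("0.7-12" = 0.7351,
                                            "12-35" = 0.1572,
                                            "35-70" = 0.0426,
                                            "70-100" = 0.0160,
                                            "100-200" = 0.0491),
                         one_over_f_exponent = 1.0,
                         units = list(),
                         events = list(iei_range = c(4, 8),
                                       move_duration_mean = 0.96,
                                       move_duration_sd = 0.1),
                         condition_label = c("control", "lesioned"),
                         component_mode = c("noise", "tone")) {
  condition_label <- match.arg(condition_label)
  component_mode <- match.arg(component_mode)
  stopifnot(duration_s > 0, lfp_fs > 0, wf_fs > 0,
            all(band_fractions >= 0), all(band_fractions <= 1),
            sum(band_fractions) <= 1 + 1e-9)
  bands <- lfp_bands()
  if (!all(names(band_fractions) %in% names(bands)))
    stop("synth_config: band_fractions names must match lfp_bands()")
  max_edge <- max(vapply(bands[names(band_fractions)], max, 0.0))
  if (lfp_fs <= 2 * max_edge)
    stop("synth_config: lfp_fs must exceed twice the highest band edge")
  structure(
    list(seed = as.integer(seed), duration_s = duration_s, lfp_fs = lfp_fs,
         wf_fs = wf_fs, band_fractions = band_fractions,
         one_over_f_exponent = one_over_f_exponent, units = units,
         events = events, condition_label = condition_label,
         component_mode = component_mode),
    class = "synth_config"
  )
}

# float32 quantization so that on-disk float32 persistence round-trips
# bit-identically.
.as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          "numeric", n = length(x), size = 4, endian = "little")
}

#' Generate a synthetic LFP trace
#'
#' Frequency-domain synthesis: each band carries a Gaussian noise component
#' whose power spectral density is a Hann envelope over the band (zero
#' density at the band edges) multiplied by a `1/f^alpha` tilt; any residual
#' power (`1 - sum(band_fractions)`) is a broadband `1/f^alpha` background
#' over 0.7-200 Hz. Each component is rescaled so its realized variance
#' matches its target fraction exactly; total variance is 1. In `"tone"`
#' mode each band is a pure sinusoid at the band's geometric center.
#'
#' @param config a [synth_config].
#' @return an [lfp_trace]; attribute `true_fractions` records the analytic
#'   per-band power fractions (including the background's in-band share).
#' @export
gen_lfp <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$lfp_fs
  n <- round(config$duration_s * fs)
  bands <- lfp_bands()[names(config$band_fractions)]
  alpha <- config$one_over_f_exponent
  freqs <- (0:(n - 1)) * fs / n
  half <- 2:(floor(n / 2)) # positive-frequency bins (excluding DC, Nyquist)
  fpos <- freqs[half]
  x <- numeric(n)
  add_component <- function(shape, target_var) {
    # shape: nonnegative PSD shape over fpos; realized variance forced to
    # target_var exactly
    if (target_var <= 0 || all(shape == 0)) return(numeric(n))
    z <- complex(real = stats::rnorm(length(half)),
                 imaginary = stats::rnorm(length(half))) / sqrt(2)
    X <- complex(real = numeric(n), imaginary = numeric(n))
    X[half] <- sqrt(shape) * z
    X[n - half + 2] <- Conj(X[half])
    comp <- Re(stats::fft(X, inverse = TRUE)) / n
    v <- mean(comp^2)
    if (v <= 0) return(numeric(n))
    comp * sqrt(target_var / v)
  }
  if (config$component_mode == "noise") {
    for (b in seq_along(bands)) {
      lo <- bands[[b]][1]; hi <- bands[[b]][2]
      # inset the component support from the band edges by (up to) the
      # multitaper estimator's half-bandwidth W = NW/window_s = 6 Hz, so the
      # injected band power stays resolvable by the analysis chain
      m <- min(4, 0.35 * (hi - lo))
      lo2 <- lo + m; hi2 <- hi - m
      shape <- numeric(length(fpos))
      inb <- fpos > lo2 & fpos < hi2
      u <- (fpos[inb] - lo2) / (hi2 - lo2)
      shape[inb] <- (0.5 - 0.5 * cos(2 * pi * u)) * fpos[inb]^(-alpha)
      x <- x + add_component(shape, config$band_fractions[b])
    }
  } else {
    t <- (0:(n - 1)) / fs
    for (b in seq_along(bands)) {
      fb <- sqrt(prod(bands[[b]]))
      # round to an integer number of cycles so windows tile coherently
      fb <- max(1, round(fb * config$duration_s)) / config$duration_s
      amp <- sqrt(2 * config$band_fractions[b])
      ph0 <- stats::runif(1, 0, 2 * pi)
      x <- x + amp * cos(2 * pi * fb * t + ph0)
    }
  }
  resid <- 1 - sum(config$band_fractions)
  union_lo <- min(vapply(bands, min, 0.0))
  union_hi <- max(vapply(bands, max, 0.0))
  if (resid > 1e-9) {
    shape <- numeric(length(fpos))
    inb <- fpos >= union_lo & fpos < union_hi
    shape[inb] <- fpos[inb]^(-alpha)
    x <- x + add_component(shape, resid)
  }
  # analytic fractions: injected band power plus the background's share
  bg_share <- vapply(bands, function(b) {
    if (resid <= 1e-9) return(0)
    num <- stats::integrate(function(f) f^(-alpha), b[1], b[2])$value
    den <- stats::integrate(function(f) f^(-alpha), union_lo, union_hi)$value
    resid * num / den
  }, 0.0)
  structure(
    lfp_trace(.as_float32(x), fs = fs, t0 = 0, channel_id = "synth1"),
    true_fractions = config$band_fractions + bg_share
  )
}

#' Generate a spike train by thinning an inhomogeneous Poisson process
#'
#' Conditional intensity
#' `lambda(t) = base_rate * g(t) * exp(kappa * cos(phi(t) - mu)) / I0(kappa)`
#' where `phi` is the instantaneous phase of the unit's coupling band
#' (bandpass + Hilbert on the supplied LFP) and `g` is the movement gain
#' inside movement windows, 1 elsewhere. Spikes are drawn by thinning a
#' homogeneous Poisson process at the bound
#' `lambda_max = base_rate * max_gain * exp(kappa) / I0(kappa)`.
#'
#' @param unit a [unit_spec].
#' @param lfp an [lfp_trace] covering the session (or `NULL` when the unit
#'   is uncoupled).
#' @param events an [event_series] (or `NULL` for no movement gain).
#' @param seed RNG seed.
#' @param t_start,t_stop train support; defaults to the LFP support.
#' @param unit_id unit identifier.
#' @param refractory_ms absolute refractory period imposed after each
#'   accepted spike, ms (default 2, matching real units' ISI floor). Set to
#'   0 for a pure thinned-Poisson calibration run (the von Mises spike-phase
#'   distribution is then exact).
#' @return a [spike_train].
#' @export
gen_spike_train <- function(unit, lfp = NULL, events = NULL, seed = 1,
                            t_start = 0,
                            t_stop = if (!is.null(lfp))
                               lfp$t0 + length(lfp$samples) / lfp$fs
                             else stop("t_stop required without an LFP"),
                            unit_id = "u1", refractory_ms = 2) {
  stopifnot(inherits(unit, "unit_spec"))
  set.seed(seed)
  kappa <- unit$kappa
  coupled <- !is.null(unit$coupling_band) && kappa > 0
  if (coupled && is.null(lfp))
    stop("gen_spike_train: coupled unit requires an LFP")
  gain_max <- max(1, unit$movement_gain)
  i0 <- besselI(kappa, 0)
  lambda_max <- unit$base_rate * gain_max * exp(kappa) / i0
  if (!is.finite(lambda_max))
    stop("gen_spike_train: thinning bound lambda_max is not finite")
  if (lambda_max == 0)
    return(spike_train(numeric(0), t_start, t_stop, unit_id,
                       unit$class_label))
  n_cand <- stats::rpois(1, lambda_max * (t_stop - t_start))
  cand <- sort(stats::runif(n_cand, t_start, t_stop))
  lambda <- rep(unit$base_rate, length(cand))
  if (coupled) {
    phi <- instantaneous_phase(lfp, unit$coupling_band)
    ph_cand <- spike_phases(cand, phi, fs = lfp$fs, t0 = lfp$t0)
    lambda <- lambda *
      exp(kappa * cos((ph_cand - unit$preferred_phase_deg) * pi / 180)) / i0
  }
  if (!is.null(events) && unit$movement_gain != 1) {
    in_move <- rep(FALSE, length(cand))
    for (r in seq_len(nrow(events$movement_windows))) {
      mw <- events$movement_windows[r, ]
      in_move <- in_move | (cand >= mw[1] & cand < mw[2])
    }
    lambda[in_move] <- lambda[in_move] * unit$movement_gain
  }
  keep <- stats::runif(length(cand)) < lambda / lambda_max
  times <- unique(cand[keep])
  if (refractory_ms > 0 && length(times) > 1) {
    dead <- refractory_ms / 1000
    ok <- logical(length(times))
    last <- -Inf
    for (i in seq_along(times)) {
      if (times[i] - last >= dead) {
        ok[i] <- TRUE
        last <- times[i]
      }
    }
    times <- times[ok]
  }
  spike_train(times, t_start, t_stop, unit_id, unit$class_label)
}

#' Generate synthetic waveform snippets
#'
#' Biphasic template (negative trough lobe followed by a positive peak
#' lobe, raised-cosine shaped) whose noiseless trough-to-peak duration is
#' `trough_to_peak_ms` rounded to the nearest sample at `wf_fs`, plus
#' additive Gaussian noise. Snippets are float32-quantized so persistence
#' round-trips exactly.
#'
#' @param unit a [unit_spec].
#' @param n_spikes number of snippets (>= 1).
#' @param seed RNG seed.
#' @param wf_fs sampling rate, Hz.
#' @param window_ms snippet window (pre, post) around the alignment point,
#'   ms.
#' @param unit_id unit identifier.
#' @return a [waveform_set].
#' @export
gen_waveforms <- function(unit, n_spikes, seed = 1, wf_fs = 40000,
                          window_ms = c(-0.4, 1.2), unit_id = "u1") {
  stopifnot(inherits(unit, "unit_spec"), n_spikes >= 1)
  set.seed(seed)
  d <- round(unit$trough_to_peak_ms * wf_fs / 1000)
  if (d < 2)
    stop("gen_waveforms: trough_to_peak_ms shorter than 2 samples at wf_fs")
  pre <- round(-window_ms[1] * wf_fs / 1000)
  post <- round(window_ms[2] * wf_fs / 1000)
  nsamp <- pre + post + 1
  i_tr <- pre + 1        # trough at the alignment point
  i_pk <- i_tr + d
  if (i_pk + d > nsamp)
    stop("gen_waveforms: snippet window too short for this duration")
  template <- numeric(nsamp)
  half_lobe <- function(center, width, idx) {
    # raised cosine lobe peaking (in magnitude) at `center`
    u <- (idx - center) / width
    ifelse(abs(u) < 1, 0.5 + 0.5 * cos(pi * u), 0)
  }
  idx <- seq_len(nsamp)
  a_tr <- min(6, d - 1)             # trough lobe half-width, samples
  template <- template - 1.0 * half_lobe(i_tr, a_tr, idx)
  rise <- pmax(0, pmin(1, (idx - (i_tr + a_tr)) / (i_pk - i_tr - a_tr)))
  fall <- half_lobe(i_pk, d, idx)
  pos <- ifelse(idx <= i_pk, 0.45 * (0.5 - 0.5 * cos(pi * rise)), 0.45 * fall)
  pos[idx <= i_tr + a_tr] <- 0
  template <- template + pos
  # guarantee the discrete argmax sits exactly at i_pk
  stopifnot(which.min(template) == i_tr,
            i_tr + which.max(template[(i_tr + 1):nsamp]) == i_pk)
  noise <- matrix(stats::rnorm(n_spikes * nsamp, sd = unit$waveform_noise_sd),
                  n_spikes, nsamp)
  snips <- .as_float32(sweep(noise, 2, template, "+"))
  dim(snips) <- c(n_spikes, nsamp)
  waveform_set(snips, fs = wf_fs, unit_id = unit_id, alignment_index = i_tr)
}

#' Generate a behavioral event schedule
#'
#' Renewal process with uniform inter-event intervals; each beam event
#' opens a movement window of Gaussian-distributed length starting at the
#' beam time. Rest intervals are the complement of the movement windows
#' with a 0.5 s guard margin.
#'
#' @param duration_s session length, seconds.
#' @param seed RNG seed.
#' @param iei_range uniform inter-event interval bounds, seconds.
#' @param move_duration_mean,move_duration_sd movement-window length
#'   distribution, seconds.
#' @return list: `events` (an [event_series]), `movement_intervals`,
#'   `rest_intervals` (2-column matrices of start/end seconds).
#' @export
gen_events <- function(duration_s, seed = 1, iei_range = c(4, 8),
                       move_duration_mean = 0.96, move_duration_sd = 0.1) {
  set.seed(seed)
  beams <- numeric(0)
  t <- 2 # leave room for the PETH pre-event window
  repeat {
    t <- t + stats::runif(1, iei_range[1], iei_range[2])
    if (t > duration_s - 3) break
    beams <- c(beams, t)
  }
  durs <- pmax(0.2, stats::rnorm(length(beams), move_duration_mean,
                                 move_duration_sd))
  mw <- cbind(beams, beams + durs)
  margin <- 0.5
  rest_edges <- c(0, as.vector(t(cbind(mw[, 1] - margin, mw[, 2] + margin))),
                  duration_s)
  rest <- matrix(rest_edges, ncol = 2, byrow = TRUE)
  rest <- rest[rest[, 2] - rest[, 1] > 0.1, , drop = FALSE]
  list(
    events = event_series(beams, mw),
    movement_intervals = unname(mw),
    rest_intervals = unname(rest)
  )
}

#' Generate a full synthetic session with ground truth
#'
#' @param config a [synth_config].
#' @return list with `bundle` (a [session_bundle]) and `ground_truth`
#'   (list: `units` data.frame of true per-unit parameters,
#'   `band_fractions` analytic LFP band fractions, `condition`).
#' @export
gen_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  lfp <- gen_lfp(config)
  ev <- gen_events(config$duration_s, seed = config$seed + 1000L,
                   iei_range = config$events$iei_range,
                   move_duration_mean = config$events$move_duration_mean,
                   move_duration_sd = config$events$move_duration_sd)
  units <- config$units
  trains <- list()
  waveforms <- list()
  gt_rows <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    uid <- sprintf("u%02d", i)
    tr <- gen_spike_train(u, lfp = lfp, events = ev$events,
                          seed = config$seed + 2000L + i,
                          t_start = 0, t_stop = config$duration_s,
                          unit_id = uid)
    wf <- gen_waveforms(u, n_spikes = max(1L, length(tr$times)),
                        seed = config$seed + 3000L + i,
                        wf_fs = config$wf_fs, unit_id = uid)
    trains[[uid]] <- tr
    waveforms[[uid]] <- wf
    gt_rows[[i]] <- data.frame(
      unit_id = uid, class_label = u$class_label, base_rate = u$base_rate,
      trough_to_peak_ms = u$trough_to_peak_ms,
      coupling_band = if (is.null(u$coupling_band)) "" else
        paste(u$coupling_band, collapse = "-"),
      kappa = u$kappa, preferred_phase_deg = u$preferred_phase_deg,
      movement_gain = u$movement_gain, stringsAsFactors = FALSE
    )
  }
  bundle <- session_bundle(
    session_id = sprintf("synth_seed%d", config$seed),
    condition = config$condition_label,
    lfp = list(synth1 = lfp),
    trains = trains,
    waveforms = waveforms,
    events = ev$events,
    rest_intervals = ev$rest_intervals,
    movement_intervals = ev$movement_intervals,
    duration_s = config$duration_s
  )
  list(
    bundle = bundle,
    ground_truth = list(
      units = if (length(gt_rows)) do.call(rbind, gt_rows) else
        data.frame(),
      band_fractions = attr(lfp, "true_fractions"),
      condition = config$condition_label
    )
  )
}

#' Template session configurations for the two study conditions
#'
#' Control and lesioned templates: LFP rest-state band fractions, BS/NS
#' baseline rates, movement gains (reaching/background rate ratios), and
#' 12-35 Hz von Mises coupling whose concentrations correspond to the two
#' conditions' movement-epoch vector lengths (R = 0.66 -> kappa = 1.8;
#' R = 0.80 -> kappa = 2.9). Per-unit biological scatter: lognormal jitter
#' on rates (10%) and kappa (8%).
#'
#' @param condition `"control"` or `"lesioned"`.
#' @param seed RNG seed (drives the jitter and everything downstream).
#' @param n_bs,n_ns number of broad- and narrow-spiking units.
#' @param duration_s session length, seconds.
#' @return a [synth_config].
#' @export
synth_template <- function(condition = c("control", "lesioned"), seed = 1,
                           n_bs = 3, n_ns = 2, duration_s = 360) {
  condition <- match.arg(condition)
  set.seed(seed + 5000L)
  p <- if (condition == "control") {
    list(fr = c("0.7-12" = 0.7351, "12-35" = 0.1572, "35-70" = 0.0426,
                "70-100" = 0.0160, "100-200" = 0.0491),
         bs_rate = 4.76, ns_rate = 7.62, bs_gain = 7.43 / 6.29,
         ns_gain = 8.78 / 7.22, bs_kappa = 1.8, ns_kappa = 2.0,
         move_mean = 0.96)
  } else {
    list(fr = c("0.7-12" = 0.5865, "12-35" = 0.2434, "35-70" = 0.0809,
                "70-100" = 0.0220, "100-200" = 0.0672),
         bs_rate = 4.15, ns_rate = 6.98, bs_gain = 6.64 / 5.33,
         ns_gain = 8.00 / 6.07, bs_kappa = 2.9, ns_kappa = 2.0,
         move_mean = 1.25)
  }
  beta <- lfp_bands()[["12-35"]]
  jit <- function(x, sd) x * exp(stats::rnorm(1, 0, sd))
  units <- c(
    lapply(seq_len(n_bs), function(i)
      unit_spec("BS", base_rate = jit(p$bs_rate, 0.10),
                trough_to_peak_ms = 0.42, coupling_band = beta,
                kappa = jit(p$bs_kappa, 0.08), preferred_phase_deg = 180,
                movement_gain = p$bs_gain, waveform_noise_sd = 0.05)),
    lapply(seq_len(n_ns), function(i)
      unit_spec("NS", base_rate = jit(p$ns_rate, 0.10),
                trough_to_peak_ms = 0.22, coupling_band = beta,
                kappa = jit(p$ns_kappa, 0.08), preferred_phase_deg = 180,
                movement_gain = p$ns_gain, waveform_noise_sd = 0.05))
  )
  synth_config(seed = seed, duration_s = duration_s,
               band_fractions = p$fr, units = units,
               events = list(iei_range = c(4, 8),
                             move_duration_mean = p$move_mean,
                             move_duration_sd = 0.1),
               condition_label = condition)
}

#' Short synthetic broadband trace with injected spikes
#'
#' For threshold-detection tests: Gaussian noise at the waveform sampling
#' rate with copies of a unit's noiseless template added at given times.
#'
#' @param unit a [unit_spec].
#' @param spike_times injection times, seconds.
#' @param duration_s trace length, seconds.
#' @param fs sampling rate, Hz.
#' @param noise_sd background noise SD (template trough amplitude is 1).
#' @param amplitude template scale factor.
#' @param seed RNG seed.
#' @return list: `x` (trace), `fs`, `spike_times` (as injected).
#' @export
gen_broadband <- function(unit, spike_times, duration_s = 1, fs = 40000,
                          noise_sd = 0.02, amplitude = 1, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- stats::rnorm(n, sd = noise_sd)
  u0 <- unit_spec(unit$class_label, unit$base_rate, unit$trough_to_peak_ms,
                  waveform_noise_sd = 0)
  template <- gen_waveforms(u0, 1, seed = 1, wf_fs = fs)$snippets[1, ]
  pre <- round(0.4 * fs / 1000)
  for (ts in spike_times) {
    i0 <- round(ts * fs) + 1 - pre
    if (i0 < 1 || i0 + length(template) - 1 > n) next
    x[i0:(i0 + length(template) - 1)] <-
      x[i0:(i0 + length(template) - 1)] + amplitude * template
  }
  list(x = x, fs = fs, spike_times = spike_times)
}
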