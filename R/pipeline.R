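#' Analyze one session
#'
#' Runs the full per-session analysis chain: unit classification
#' (trough-to-peak + refractory criterion), ISI pattern metrics per
#' behavioral state, PETH and modulation test per unit, multitaper relative
#' band power of the rest-state LFP (3 s blocks averaged), and spike-field
#' coupling (band-mean coherence and bandpass-Hilbert phase locking) per
#' unit for rest and movement epochs.
#'
#' @param bundle a [session_bundle].
#' @param coupling_bands named list of bands for the coupling analyses.
#' @param alpha significance level.
#' @param peth_window PETH window, seconds.
#' @return object of class `session_report`: data.frames `classification`,
#'   `metrics`, `peth`, `band_power`, `coupling`.
#' @export
analyze_session <- function(bundle,
                            coupling_bands =
                              lfp_bands()[c("0.7-12", "12-35", "35-70")],
                            alpha = 0.05,
                            peth_window = c(-1.0, 1.5)) {
  stopifnot(inherits(bundle, "session_bundle"))
  sid <- bundle$session_id
  cls <- classify_units(bundle$waveforms, bundle$trains)
  if (nrow(cls)) {
    cls <- cbind(session_id = sid, condition = bundle$condition, cls)
  }
  class_of <- stats::setNames(cls$class_label, cls$unit_id)

  states <- list(rest = bundle$rest_intervals,
                 movement = bundle$movement_intervals)
  metrics <- list()
  for (u in names(bundle$trains)) {
    tr <- bundle$trains[[u]]
    for (st in names(states)) {
      iv <- states[[st]]
      if (is.null(iv) || nrow(iv) == 0) next
      r <- restrict_train(tr, iv)
      sub <- spike_train(r$times, min(iv), max(iv), u, tr$class_label)
      stats_u <- isi_stats(sub, interval = c(0, r$total_time))
      # rate over the state's summed time, not the span
      stats_u$mean_rate <- length(r$times) / r$total_time
      metrics[[paste(u, st)]] <- data.frame(
        session_id = sid, condition = bundle$condition, unit_id = u,
        class_label = class_of[[u]], state = st,
        n_spikes = stats_u$n_spikes, rate = stats_u$mean_rate,
        cv = stats_u$cv, mode_s = stats_u$mode_s,
        asymmetry_index = stats_u$asymmetry_index,
        stringsAsFactors = FALSE)
    }
  }
  metrics <- if (length(metrics)) do.call(rbind, metrics) else data.frame()
  rownames(metrics) <- NULL

  peth_rows <- list()
  if (!is.null(bundle$events) && length(bundle$events$beam_times) >= 10) {
    for (u in names(bundle$trains)) {
      pr <- build_peth(bundle$trains[[u]], bundle$events,
                       window = peth_window)
      mt <- modulation_test(pr, alpha = alpha)
      peth_rows[[u]] <- data.frame(
        session_id = sid, condition = bundle$condition, unit_id = u,
        class_label = class_of[[u]], n_trials = mt$n_trials,
        baseline_rate = mt$baseline_rate,
        movement_rate = mt$movement_rate,
        modulation_p = mt$p, modulated = mt$modulated,
        stringsAsFactors = FALSE)
    }
  }
  peth <- if (length(peth_rows)) do.call(rbind, peth_rows) else data.frame()
  rownames(peth) <- NULL

  # rest-state band power: 3 s blocks of rest data, block PSDs averaged
  band_rows <- list()
  for (ch in names(bundle$lfp)) {
    trace <- lfp_preprocess(bundle$lfp[[ch]])
    segs <- .state_segments(trace, bundle$rest_intervals, block_s = 3)
    if (length(segs) == 0) next
    psds <- lapply(segs, multitaper_psd, fs = trace$fs)
    avg <- psds[[1]]
    avg$power <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
    bp <- relative_band_power(avg)
    band_rows[[ch]] <- data.frame(
      session_id = sid, condition = bundle$condition, channel = ch,
      band = names(bp$fractions), fraction = unname(bp$fractions),
      stringsAsFactors = FALSE)
  }
  band_power <- if (length(band_rows)) do.call(rbind, band_rows) else
    data.frame()
  rownames(band_power) <- NULL

  coup_rows <- list()
  if (length(bundle$lfp)) {
    ch <- names(bundle$lfp)[1]
    trace <- lfp_preprocess(bundle$lfp[[ch]])
    phases <- lapply(coupling_bands, function(b)
      instantaneous_phase(trace, b))
    for (u in names(bundle$trains)) {
      tr <- bundle$trains[[u]]
      coh <- tryCatch(
        spike_field_coherence(tr, trace, bands = coupling_bands),
        error = function(e) NULL)
      for (st in names(states)) {
        iv <- states[[st]]
        if (is.null(iv) || nrow(iv) == 0) next
        times <- restrict_train(tr, iv)$times
        for (b in names(coupling_bands)) {
          ang <- spike_phases(times, phases[[b]], fs = trace$fs,
                              t0 = trace$t0)
          pl <- phase_lock_summary(ang, band = coupling_bands[[b]],
                                   alpha = alpha)
          coup_rows[[paste(u, st, b)]] <- data.frame(
            session_id = sid, condition = bundle$condition, unit_id = u,
            class_label = class_of[[u]], state = st, band = b,
            n_spikes = pl$n_spikes,
            band_mean_coherence = if (is.null(coh)) NA_real_ else
              unname(coh$band_means[b]),
            mean_angle_deg = pl$mean_angle_deg,
            vector_length = pl$vector_length,
            rayleigh_p = pl$rayleigh_p,
            admissible = pl$admissible, locked = pl$locked,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  coupling <- if (length(coup_rows)) do.call(rbind, coup_rows) else
    data.frame()
  rownames(coupling) <- NULL

  structure(
    list(session_id = sid, condition = bundle$condition,
         classification = cls, metrics = metrics, peth = peth,
         band_power = band_power, coupling = coupling,
         params = list(alpha = alpha, peth_window = peth_window,
                       coupling_bands = coupling_bands)),
    class = "session_report"
  )
}

# cut the samples of `trace` inside the given intervals into blocks of
# block_s seconds (trailing partial blocks dropped)
.state_segments <- function(trace, intervals, block_s = 3) {
  if (is.null(intervals) || nrow(intervals) == 0) return(list())
  fs <- trace$fs
  nblock <- round(block_s * fs)
  segs <- list()
  for (r in seq_len(nrow(intervals))) {
    i0 <- max(1L, floor((intervals[r, 1] - trace$t0) * fs) + 1L)
    i1 <- min(length(trace$samples),
              floor((intervals[r, 2] - trace$t0) * fs))
    len <- i1 - i0 + 1
    if (len < nblock) next
    for (b in seq_len(len %/% nblock)) {
      segs[[length(segs) + 1]] <-
        trace$samples[(i0 + (b - 1) * nblock):(i0 + b * nblock - 1)]
    }
  }
  segs
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf(
    "<session_report %s (%s): %d units, %d PETHs, %d coupling rows>\n",
    x$session_id, x$condition, nrow(x$classification), nrow(x$peth),
    nrow(x$coupling)))
  invisible(x)
}

#' Run the full pipeline over a cohort of sessions
#'
#' Loads (or accepts in-memory) session bundles, analyzes each with
#' [analyze_session], stacks the per-unit tables, and computes the group
#' comparisons: BS and NS rest firing rate (control vs lesioned,
#' Mann-Whitney), repeated-measures ANOVA on the band-power fractions with
#' per-band contrasts, a two-way group x behavior ANOVA on BS rates
#' (baseline vs reaching), and movement-epoch vector length at 12-35 Hz per
#' class. Deterministic given inputs: rerunning on the same sessions
#' reproduces identical tables.
#'
#' @param sessions character vector of session directories, or a list of
#'   [session_bundle]s.
#' @param out_dir optional output directory for the CSV report tables.
#' @param alpha significance level.
#' @param verbose print progress to standard error.
#' @return object of class `pipeline_report`: stacked tables
#'   (`classification`, `metrics`, `peth`, `band_power`, `coupling`) and
#'   `comparisons` (named list of [group_compare] results / Mann-Whitney
#'   rows), plus `findings` (data.frame of the headline direction-of-effect
#'   checks).
#' @export
run_pipeline <- function(sessions, out_dir = NULL, alpha = 0.05,
                         verbose = FALSE) {
  if (length(sessions) == 0) stop("run_pipeline: no sessions given")
  bundles <- lapply(sessions, function(s) {
    if (inherits(s, "session_bundle")) s else load_session(s)
  })
  reports <- list()
  for (b in bundles) {
    if (verbose) message("analyzing ", b$session_id)
    reports[[b$session_id]] <- tryCatch(
      analyze_session(b, alpha = alpha),
      error = function(e) {
        message("session ", b$session_id, " failed: ", conditionMessage(e))
        NULL
      })
  }
  failed <- vapply(reports, is.null, TRUE)
  if (all(failed)) stop("run_pipeline: every session failed")
  reports <- reports[!failed]
  stack <- function(field) {
    tabs <- lapply(reports, `[[`, field)
    tabs <- tabs[vapply(tabs, nrow, 0L) > 0]
    if (!length(tabs)) return(data.frame())
    out <- do.call(rbind, tabs)
    rownames(out) <- NULL
    out
  }
  classification <- stack("classification")
  metrics <- stack("metrics")
  peth <- stack("peth")
  band_power <- stack("band_power")
  coupling <- stack("coupling")

  comparisons <- list()
  findings <- list()
  two_groups <- length(unique(metrics$condition)) == 2
  if (two_groups) {
    # rest rate per class, control vs lesioned
    for (cl in c("BS", "NS")) {
      sub <- metrics[metrics$state == "rest" & metrics$class_label == cl, ]
      if (!nrow(sub)) next
      x <- sub$rate[sub$condition == "control"]
      y <- sub$rate[sub$condition == "lesioned"]
      if (!length(x) || !length(y)) next
      mw <- mann_whitney_u(x, y)
      comparisons[[paste0(cl, "_rest_rate")]] <- data.frame(
        metric = paste0(cl, " rest rate"),
        mean_control = mean(x), sem_control = stats::sd(x) / sqrt(length(x)),
        n_control = length(x),
        mean_lesioned = mean(y), sem_lesioned = stats::sd(y) / sqrt(length(y)),
        n_lesioned = length(y), U = mw$U, p = mw$p)
      if (cl == "BS")
        findings$bs_rate_reduced <- data.frame(
          finding = "BS rest rate reduced in lesioned",
          observed = mean(y) < mean(x), p = mw$p,
          significant = mw$p < alpha)
    }
    # band-power fractions: repeated measures over bands, session = subject
    if (nrow(band_power)) {
      bp <- data.frame(value = band_power$fraction,
                       group = band_power$condition,
                       band = band_power$band,
                       subject = band_power$session_id)
      comparisons$band_power <- group_compare(bp, design = "repeated",
                                              alpha = alpha)
      beta <- comparisons$band_power$pairwise
      beta <- beta[grepl("@ 12-35", beta$contrast), ]
      x <- bp$value[bp$band == "12-35" & bp$group == "control"]
      y <- bp$value[bp$band == "12-35" & bp$group == "lesioned"]
      findings$beta_power_elevated <- data.frame(
        finding = "12-35 Hz relative power elevated in lesioned",
        observed = mean(y) > mean(x), p = beta$p[1],
        significant = beta$corrected_p[1] < alpha)
    }
    # two-way ANOVA on BS rates: group x behavior (baseline vs reaching)
    if (nrow(peth)) {
      bs <- peth[peth$class_label == "BS", ]
      if (nrow(bs)) {
        tw <- rbind(
          data.frame(value = bs$baseline_rate, group = bs$condition,
                     behavior = "background"),
          data.frame(value = bs$movement_rate, group = bs$condition,
                     behavior = "reaching"))
        comparisons$bs_rate_twoway <- tryCatch(
          group_compare(tw, design = "twoway", alpha = alpha),
          error = function(e) NULL)
      }
    }
    # movement-epoch phase locking at 12-35 Hz per class
    if (nrow(coupling)) {
      for (cl in c("BS", "NS")) {
        sub <- coupling[coupling$state == "movement" &
                          coupling$band == "12-35" &
                          coupling$class_label == cl &
                          coupling$admissible, ]
        if (!nrow(sub)) next
        x <- sub$vector_length[sub$condition == "control"]
        y <- sub$vector_length[sub$condition == "lesioned"]
        if (!length(x) || !length(y)) next
        mw <- mann_whitney_u(x, y)
        comparisons[[paste0(cl, "_movement_vector_length")]] <- data.frame(
          metric = paste0(cl, " movement vector length (12-35 Hz)"),
          mean_control = mean(x),
          sem_control = stats::sd(x) / sqrt(length(x)), n_control = length(x),
          mean_lesioned = mean(y),
          sem_lesioned = stats::sd(y) / sqrt(length(y)),
          n_lesioned = length(y), U = mw$U, p = mw$p)
        if (cl == "BS")
          findings$bs_vector_length_elevated <- data.frame(
            finding = "BS movement vector length (12-35 Hz) elevated in lesioned",
            observed = mean(y) > mean(x), p = mw$p,
            significant = mw$p < alpha)
      }
    }
  }
  findings <- if (length(findings)) {
    out <- do.call(rbind, findings)
    rownames(out) <- NULL
    out
  } else data.frame()

  report <- structure(
    list(classification = classification, metrics = metrics, peth = peth,
         band_power = band_power, coupling = coupling,
         comparisons = comparisons, findings = findings,
         n_sessions = length(reports), alpha = alpha),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (f in c("classification", "metrics", "peth", "band_power",
                "coupling", "findings")) {
      utils::write.csv(report[[f]], file.path(out_dir, paste0(f, ".csv")),
                       row.names = FALSE)
    }
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d sessions, %d units>\n",
              x$n_sessions, nrow(x$classification)))
  if (nrow(x$findings)) {
    cat("Findings:\n")
    print(x$findings, digits = 3)
  }
  invisible(x)
}
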