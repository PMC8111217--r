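#' Session bundle
#'
#' One recording session: LFP traces, spike trains, waveform sets, the
#' behavioral event series, rest/movement state intervals, and a condition
#' label.
#'
#' @param session_id session identifier.
#' @param condition `"control"` or `"lesioned"`.
#' @param lfp named list of [lfp_trace]s.
#' @param trains named list of [spike_train]s.
#' @param waveforms named list of [waveform_set]s (same names as `trains`).
#' @param events an [event_series] or `NULL`.
#' @param rest_intervals,movement_intervals 2-column matrices of
#'   (start, end) seconds.
#' @param duration_s session length, seconds.
#' @return object of class `session_bundle`.
#' @export
session_bundle <- function(session_id, condition, lfp, trains, waveforms,
                           events = NULL, rest_intervals = NULL,
                           movement_intervals = NULL, duration_s) {
  condition <- match.arg(condition, c("control", "lesioned"))
  stopifnot(is.list(lfp), is.list(trains), is.list(waveforms),
            duration_s > 0)
  if (!identical(sort(names(trains)), sort(names(waveforms))))
    stop("session_bundle: trains and waveforms must cover the same units")
  for (iv in list(rest_intervals, movement_intervals)) {
    if (!is.null(iv) && nrow(iv) > 0 &&
        (any(iv < -1e-9) || any(iv > duration_s + 1e-9)))
      stop("session_bundle: state intervals outside [0, duration]")
  }
  structure(
    list(session_id = session_id, condition = condition, lfp = lfp,
         trains = trains, waveforms = waveforms, events = events,
         rest_intervals = rest_intervals,
         movement_intervals = movement_intervals,
         duration_s = duration_s),
    class = "session_bundle"
  )
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf(
    "<session_bundle %s (%s): %d LFP channel(s), %d unit(s), %d trial(s), %.0f s>\n",
    x$session_id, x$condition, length(x$lfp), length(x$trains),
    if (is.null(x$events)) 0L else length(x$events$beam_times),
    x$duration_s))
  invisible(x)
}

.write_f32 <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
}

.read_f32 <- function(path, n) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "numeric", n = n, size = 4, endian = "little")
}

.fmt17 <- function(x) sprintf("%.17g", x)

#' Save a session bundle to a directory
#'
#' Layout: `manifest.json`; `lfp/<chan>.f32` (little-endian float32);
#' `units/<unit>.txt` (one ascending ASCII timestamp per line, seconds);
#' `waveforms/<unit>.f32` (row-major float32, shape in the manifest);
#' `events.csv`; `intervals.csv`. The round-trip through [load_session] is
#' lossless (float32 payloads are float32 in memory by construction of the
#' generator; timestamps are written with 17 significant digits).
#'
#' @param bundle a [session_bundle].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_session <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "lfp"), showWarnings = FALSE)
  dir.create(file.path(dir, "units"), showWarnings = FALSE)
  dir.create(file.path(dir, "waveforms"), showWarnings = FALSE)
  manifest <- list(
    session_id = bundle$session_id,
    condition = bundle$condition,
    duration_s = bundle$duration_s,
    lfp = lapply(bundle$lfp, function(tr)
      list(fs = tr$fs, t0 = tr$t0, n = length(tr$samples))),
    units = lapply(bundle$trains, function(tr)
      list(t_start = tr$t_start, t_stop = tr$t_stop,
           n = length(tr$times), class_label = tr$class_label)),
    waveforms = lapply(bundle$waveforms, function(wf)
      list(fs = wf$fs, n_spikes = nrow(wf$snippets),
           n_samples = ncol(wf$snippets),
           alignment_index = wf$alignment_index))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ch in names(bundle$lfp))
    .write_f32(bundle$lfp[[ch]]$samples, file.path(dir, "lfp",
                                                   paste0(ch, ".f32")))
  for (u in names(bundle$trains))
    writeLines(.fmt17(bundle$trains[[u]]$times),
               file.path(dir, "units", paste0(u, ".txt")))
  for (u in names(bundle$waveforms))
    .write_f32(t(bundle$waveforms[[u]]$snippets),
               file.path(dir, "waveforms", paste0(u, ".f32")))
  ev <- bundle$events
  ev_df <- if (is.null(ev) || length(ev$beam_times) == 0) {
    data.frame(trial_id = character(0), beam_time_s = character(0),
               move_start_s = character(0), move_end_s = character(0))
  } else {
    data.frame(trial_id = ev$labels,
               beam_time_s = .fmt17(ev$beam_times),
               move_start_s = .fmt17(ev$movement_windows[, 1]),
               move_end_s = .fmt17(ev$movement_windows[, 2]))
  }
  utils::write.csv(ev_df, file.path(dir, "events.csv"), row.names = FALSE)
  iv_df <- rbind(
    if (!is.null(bundle$rest_intervals) && nrow(bundle$rest_intervals))
      data.frame(state = "rest",
                 start_s = .fmt17(bundle$rest_intervals[, 1]),
                 end_s = .fmt17(bundle$rest_intervals[, 2])),
    if (!is.null(bundle$movement_intervals) &&
        nrow(bundle$movement_intervals))
      data.frame(state = "movement",
                 start_s = .fmt17(bundle$movement_intervals[, 1]),
                 end_s = .fmt17(bundle$movement_intervals[, 2]))
  )
  if (is.null(iv_df))
    iv_df <- data.frame(state = character(0), start_s = character(0),
                        end_s = character(0))
  utils::write.csv(iv_df, file.path(dir, "intervals.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a session bundle from a directory
#'
#' Validates the layout written by [save_session]: every unit in the
#' manifest must have a timestamp file, sampling rates must be positive,
#' and spike times strictly ascending; violations raise an error naming the
#' offending record.
#'
#' @param dir session directory.
#' @return a [session_bundle].
#' @export
load_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("load_session: no manifest.json in ", dir)
  m <- jsonlite::read_json(mpath, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lfp <- list()
  for (ch in names(m$lfp)) {
    info <- m$lfp[[ch]]
    if (is.null(info$fs) || info$fs <= 0)
      stop("load_session: non-positive fs for LFP channel ", ch)
    path <- file.path(dir, "lfp", paste0(ch, ".f32"))
    if (!file.exists(path)) stop("load_session: missing LFP file for ", ch)
    lfp[[ch]] <- lfp_trace(.read_f32(path, info$n), fs = info$fs,
                           t0 = info$t0, channel_id = ch)
  }
  trains <- list()
  for (u in names(m$units)) {
    info <- m$units[[u]]
    path <- file.path(dir, "units", paste0(u, ".txt"))
    if (!file.exists(path))
      stop("load_session: manifest lists unit ", u,
           " but its timestamp file is missing")
    times <- as.numeric(readLines(path))
    if (length(times) && is.unsorted(times, strictly = TRUE))
      stop("load_session: spike times not strictly ascending for unit ", u)
    trains[[u]] <- spike_train(times, info$t_start, info$t_stop, u,
                               info$class_label %||% NA_character_)
  }
  waveforms <- list()
  for (u in names(m$waveforms)) {
    info <- m$waveforms[[u]]
    path <- file.path(dir, "waveforms", paste0(u, ".f32"))
    if (!file.exists(path))
      stop("load_session: missing waveform file for unit ", u)
    v <- .read_f32(path, info$n_spikes * info$n_samples)
    waveforms[[u]] <- waveform_set(
      matrix(v, info$n_spikes, info$n_samples, byrow = TRUE),
      fs = info$fs, unit_id = u, alignment_index = info$alignment_index)
  }
  ev_df <- utils::read.csv(file.path(dir, "events.csv"),
                           colClasses = c(trial_id = "character"))
  events <- if (nrow(ev_df) == 0) NULL else
    event_series(as.numeric(ev_df$beam_time_s),
                 cbind(as.numeric(ev_df$move_start_s),
                       as.numeric(ev_df$move_end_s)),
                 labels = ev_df$trial_id)
  iv_df <- utils::read.csv(file.path(dir, "intervals.csv"))
  pick <- function(state) {
    sub <- iv_df[iv_df$state == state, , drop = FALSE]
    if (nrow(sub) == 0) return(matrix(numeric(0), 0, 2))
    unname(cbind(as.numeric(sub$start_s), as.numeric(sub$end_s)))
  }
  session_bundle(m$session_id, m$condition, lfp, trains, waveforms, events,
                 pick("rest"), pick("movement"), m$duration_s)
}
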