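#' Core sweep and pair-recording containers
#'
#' A `sweep_record` holds one stimulus-locked voltage-clamp current trace.
#' Samples keep the raw amplifier sign (inward IPSC = negative current, pA);
#' every *reported* IPSC amplitude or charge downstream is a positive,
#' sign-inverted magnitude. Time is measured in ms from sweep start, with the
#' stimulus at `stim_time`.
#'
#' @param samples numeric vector of currents in pA (raw sign).
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param stim_time stimulus onset in ms from sweep start.
#' @param ap_time presynaptic action-potential peak time in ms, or `NA` if the
#'   stimulus failed to evoke a spike.
#' @param labels list with elements `ap_success` (logical),
#'   `ipsc_success` (logical or `NA` = undetermined) and `event_class`
#'   (one of `"phasic"`, `"delayed"`, `"failure"`, `"undetermined"`).
#' @return an object of class `sweep_record`.
#' @export
sweep_record <- function(samples, sampling_rate, stim_time,
                         ap_time = NA_real_, labels = NULL) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stopf("samples must be a numeric vector")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stopf("sampling_rate must be > 0")
  dur <- index_to_ms(length(samples), sampling_rate)
  if (stim_time < 0 || stim_time > dur)
    stopf("stim_time (%.3f ms) outside sweep [0, %.3f] ms", stim_time, dur)
  if (!is.na(ap_time) && ap_time < stim_time)
    stopf("ap_time (%.3f) precedes stim_time (%.3f)", ap_time, stim_time)
  labels <- labels %||% list(ap_success = !is.na(ap_time),
                             ipsc_success = NA,
                             event_class = "undetermined")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate,
                 stim_time = stim_time,
                 ap_time = ap_time,
                 labels = labels),
            class = "sweep_record")
}

#' @export
print.sweep_record <- function(x, ...) {
  cat(sprintf("<sweep_record> %d samples @ %g kHz, stim %.2f ms, AP %s\n",
              length(x$samples), x$sampling_rate / 1000, x$stim_time,
              if (is.na(x$ap_time)) "failure" else sprintf("%.2f ms", x$ap_time)))
  invisible(x)
}

sweep_duration_ms <- function(sweep) {
  index_to_ms(length(sweep$samples), sweep$sampling_rate)
}

#' One Golgi-to-granule-cell pair: an ordered set of sweeps plus metadata
#'
#' @param pair_id character identifier.
#' @param sweeps list of [sweep_record] objects sharing one sampling rate.
#' @param phenotype presynaptic phenotype: `"GlyT2_pos"`, `"GlyT2_neg"` or
#'   `"unknown"`.
#' @param protocol `"optogenetic_0p37Hz"` (single-cell flashes) or
#'   `"electrical_10Hz"` (axonal train stimulation).
#' @param connected logical connectivity call, or `NA` if not yet classified.
#' @return an object of class `pair_recording`.
#' @export
pair_recording <- function(pair_id, sweeps,
                           phenotype = c("unknown", "GlyT2_pos", "GlyT2_neg"),
                           protocol = c("optogenetic_0p37Hz", "electrical_10Hz"),
                           connected = NA) {
  phenotype <- match.arg(phenotype)
  protocol <- match.arg(protocol)
  if (!length(sweeps) || !all(vapply(sweeps, inherits, TRUE, "sweep_record")))
    stopf("sweeps must be a non-empty list of sweep_record objects")
  fs <- unique(vapply(sweeps, function(s) s$sampling_rate, 0))
  if (length(fs) != 1L) stopf("all sweeps in a pair must share sampling_rate")
  structure(list(pair_id = as.character(pair_id), phenotype = phenotype,
                 protocol = protocol, sweeps = sweeps, connected = connected),
            class = "pair_recording")
}

#' @export
print.pair_recording <- function(x, ...) {
  cat(sprintf("<pair_recording> %s [%s, %s]: %d sweeps, connected = %s\n",
              x$pair_id, x$phenotype, x$protocol, length(x$sweeps),
              as.character(x$connected)))
  invisible(x)
}

#' Half-open analysis window in ms
#'
#' @param start,end window bounds in ms, interpreted as `[start, end)`.
#' @return an object of class `time_window`.
#' @export
time_window <- function(start, end) {
  if (!is.finite(start) || !is.finite(end) || end <= start)
    stopf("time_window requires end > start")
  structure(list(start = start, end = end), class = "time_window")
}

as_time_window <- function(x) {
  if (inherits(x, "time_window")) return(x)
  if (is.numeric(x) && length(x) == 2L) return(time_window(x[1L], x[2L]))
  stopf("expected a time_window or a numeric length-2 vector")
}

# -------------------------------------------------------------------------
# Archive I/O. Plain-text directory layout (one long-format CSV per pair):
#   manifest.csv : pair_id, phenotype, protocol, sampling_rate_hz,
#                  stim_time_ms, n_sweeps, connected
#   sweeps_<id>.csv : trial, time_ms, current_pA   (trial-major, full precision)
#   ap_times_<id>.csv : trial, ap_time_ms          (NA = AP failure)
#   labels_<id>.csv : trial, ap_success, ipsc_success, event_class  (optional)

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a set of pair recordings to a plain-text archive
#'
#' Samples are serialised with 17 significant digits so that
#' `read_pair_archive(write_pair_archive(x))` round-trips doubles bit-exactly.
#'
#' @param pairs non-empty list of [pair_recording] objects.
#' @param path directory to create.
#' @param overwrite overwrite an existing archive directory.
#' @return `path`, invisibly.
#' @export
write_pair_archive <- function(pairs, path, overwrite = FALSE) {
  if (!length(pairs)) stopf("pairs must be a non-empty list")
  if (inherits(pairs, "pair_recording")) pairs <- list(pairs)
  if (!all(vapply(pairs, inherits, TRUE, "pair_recording")))
    stopf("pairs must be pair_recording objects")
  if (dir.exists(path)) {
    if (!overwrite) stopf("archive '%s' exists; set overwrite = TRUE", path)
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  man <- do.call(rbind, lapply(pairs, function(p) {
    s1 <- p$sweeps[[1L]]
    data.frame(pair_id = p$pair_id, phenotype = p$phenotype,
               protocol = p$protocol, sampling_rate_hz = s1$sampling_rate,
               stim_time_ms = s1$stim_time, n_sweeps = length(p$sweeps),
               connected = p$connected, stringsAsFactors = FALSE)
  }))
  utils::write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE)
  for (p in pairs) {
    fs <- p$sweeps[[1L]]$sampling_rate
    ns <- length(p$sweeps[[1L]]$samples)
    lines <- c("trial,time_ms,current_pA")
    tms <- fmt17(index_to_ms(seq_len(ns), fs))
    for (i in seq_along(p$sweeps)) {
      sw <- p$sweeps[[i]]
      if (length(sw$samples) != ns)
        stopf("pair %s: sweep %d length differs", p$pair_id, i)
      lines <- c(lines, paste(i, tms, fmt17(sw$samples), sep = ","))
    }
    writeLines(lines, file.path(path, sprintf("sweeps_%s.csv", p$pair_id)))
    ap <- vapply(p$sweeps, function(s) s$ap_time, 0)
    writeLines(c("trial,ap_time_ms",
                 paste(seq_along(ap), fmt17(ap), sep = ",")),
               file.path(path, sprintf("ap_times_%s.csv", p$pair_id)))
    lab <- do.call(rbind, lapply(seq_along(p$sweeps), function(i) {
      l <- p$sweeps[[i]]$labels
      data.frame(trial = i, ap_success = l$ap_success,
                 ipsc_success = l$ipsc_success, event_class = l$event_class,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(lab, file.path(path, sprintf("labels_%s.csv", p$pair_id)),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read a pair-recording archive written by [write_pair_archive()]
#'
#' @param path archive directory.
#' @return list of [pair_recording] objects.
#' @export
read_pair_archive <- function(path) {
  man_path <- file.path(path, "manifest.csv")
  if (!file.exists(man_path)) stopf("no manifest.csv under '%s'", path)
  man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  if (!"sampling_rate_hz" %in% names(man))
    stopf("archive manifest lacks sampling_rate_hz: not a valid archive")
  if (!"phenotype" %in% names(man) || anyNA(man$phenotype)) {
    warnf("archive lacks phenotype for some pairs; defaulting to 'unknown'")
    if (!"phenotype" %in% names(man)) man$phenotype <- "unknown"
    man$phenotype[is.na(man$phenotype)] <- "unknown"
  }
  lapply(seq_len(nrow(man)), function(r) {
    id <- man$pair_id[r]
    fs <- man$sampling_rate_hz[r]
    sw <- utils::read.csv(file.path(path, sprintf("sweeps_%s.csv", id)),
                          stringsAsFactors = FALSE)
    ap <- utils::read.csv(file.path(path, sprintf("ap_times_%s.csv", id)),
                          stringsAsFactors = FALSE)
    lab_path <- file.path(path, sprintf("labels_%s.csv", id))
    lab <- if (file.exists(lab_path))
      utils::read.csv(lab_path, stringsAsFactors = FALSE) else NULL
    trials <- sort(unique(sw$trial))
    lens <- tapply(sw$trial, sw$trial, length)
    if (length(unique(lens)) != 1L)
      stopf("pair %s: inconsistent sweep lengths", id)
    sweeps <- lapply(trials, function(i) {
      sel <- sw$trial == i
      l <- if (!is.null(lab)) {
        lr <- lab[lab$trial == i, , drop = FALSE]
        list(ap_success = as.logical(lr$ap_success[1L]),
             ipsc_success = if (is.na(lr$ipsc_success[1L])) NA
                            else as.logical(lr$ipsc_success[1L]),
             event_class = as.character(lr$event_class[1L]))
      } else NULL
      sweep_record(sw$current_pA[sel], fs, man$stim_time_ms[r],
                   ap_time = ap$ap_time_ms[match(i, ap$trial)], labels = l)
    })
    pair_recording(id, sweeps, phenotype = man$phenotype[r],
                   protocol = man$protocol[r],
                   connected = if ("connected" %in% names(man))
                     man$connected[r] else NA)
  })
}

# -------------------------------------------------------------------------

#' Segment a continuous train recording into stimulus-locked sweeps
#'
#' Cuts a continuous current trace (e.g. a 10 Hz electrical-stimulation
#' recording) into one sweep per stimulus. `window` is expressed relative to
#' each stimulus (`start` is usually negative to keep a pre-stimulus
#' baseline); within each sweep the stimulus sits at `-window$start` ms.
#'
#' @param samples continuous current trace in pA.
#' @param sampling_rate Hz.
#' @param stim_times stimulus onsets in ms from trace start, sorted ascending.
#' @param window [time_window] (or numeric length 2) relative to the stimulus.
#' @return list of [sweep_record] objects, one per stimulus.
#' @export
segment_train <- function(samples, sampling_rate, stim_times, window) {
  window <- as_time_window(window)
  if (is.unsorted(stim_times)) stopf("stim_times must be sorted ascending")
  isi <- if (length(stim_times) > 1L) min(diff(stim_times)) else Inf
  if (window$end - window$start > isi + 1e-9)
    stopf("window (%.1f ms) longer than inter-stimulus interval (%.1f ms)",
          window$end - window$start, isi)
  n <- length(samples)
  lapply(stim_times, function(st) {
    i0 <- ms_to_index(st + window$start, sampling_rate)
    i1 <- ms_to_index(st + window$end, sampling_rate) - 1L
    if (i0 < 1L || i1 > n)
      stopf("window around stimulus at %.1f ms falls outside the trace", st)
    sweep_record(samples[i0:i1], sampling_rate, stim_time = -window$start)
  })
}

#' Detect the presynaptic action potential in a loose-patch sweep
#'
#' Loose cell-attached spikes are scored from the smoothed first derivative of
#' the current: the spike time is the extremum of the derivative within the
#' search window, provided it exceeds `k` standard deviations of the
#' pre-stimulus derivative noise. Trials with no crossing are AP failures.
#'
#' @param sweep a [sweep_record] from a loose-patch recording.
#' @param search [time_window] to search, in sweep time (ms); default
#'   `[stim_time, stim_time + 10)`.
#' @param k threshold in units of pre-stimulus derivative SD (default 5).
#' @param smooth_ms boxcar width applied to the derivative (default 0.25 ms).
#' @return spike time in ms, or `NA_real_` for an AP failure.
#' @export
detect_ap_time <- function(sweep, search = NULL, k = 5, smooth_ms = 0.25) {
  fs <- sweep$sampling_rate
  search <- if (is.null(search))
    time_window(sweep$stim_time, min(sweep$stim_time + 10, sweep_duration_ms(sweep)))
  else as_time_window(search)
  if (search$end - search$start < 1) stopf("search window shorter than 1 ms")
  d <- c(0, diff(sweep$samples)) * fs / 1000      # pA/ms, aligned to samples
  d <- boxcar(d, round(smooth_ms * fs / 1000))
  pre <- d[seq_len(max(2L, ms_to_index(sweep$stim_time, fs) - 1L))]
  noise_sd <- stats::sd(pre)
  if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- .Machine$double.eps
  i0 <- max(1L, ms_to_index(search$start, fs))
  i1 <- min(length(d), ms_to_index(search$end, fs) - 1L)
  seg <- d[i0:i1]
  if (max(abs(seg)) <= k * noise_sd) return(NA_real_)
  index_to_ms(i0 - 1L + which.max(abs(seg)), fs)
}
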