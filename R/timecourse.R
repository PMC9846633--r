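# Pharmacology time-course analysis of electrically evoked IPSC trains.
# The working quantity is QeIPSC: the charge of the average of 100
# consecutive eIPSCs (one 10-s bin at 10 Hz), normalised by the mean over
# the first minutes of baseline.

# charge (pC), peak (pA) and peak time of an averaged eIPSC sweep:
# local baseline over the 10 ms before the stimulus, integral from the
# stimulus to the end of the sweep, peak within 15 ms of the stimulus
eipsc_measures <- function(sweep) {
  fs <- sweep$sampling_rate
  st <- sweep$stim_time
  ib0 <- max(1L, ms_to_index(st - 10, fs))
  ib1 <- max(ib0 + 1L, ms_to_index(st, fs) - 1L)
  base <- mean(sweep$samples[ib0:ib1])
  i0 <- ms_to_index(st, fs)
  n <- length(sweep$samples)
  q <- -trapz(sweep$samples[i0:n] - base, 1000 / fs) / 1000
  pk <- peak_and_delay(sweep, ap_time = st,
                       search = c(st, min(st + 15, sweep_duration_ms(sweep))))
  list(q = q, i = pk$peak_amp, peak_time = pk$peak_time)
}

#' QeIPSC time series from a segmented 10 Hz train
#'
#' Averages consecutive sweeps in bins of `bin_sweeps` (100 sweeps = one
#' 10-s bin at 10 Hz), measures the charge and peak of each averaged eIPSC,
#' and normalises the charge by the mean over the baseline bins.
#'
#' @param sweeps list of [sweep_record] from [segment_train()]; each sweep
#'   must keep >= 10 ms of pre-stimulus baseline.
#' @param bin_sweeps sweeps per bin (default 100).
#' @param stim_rate stimulation rate in Hz (default 10).
#' @param baseline_min baseline duration used for normalisation (default 3).
#' @return data.frame of class `qeipsc_series`: `bin`, `time_min` (bin end),
#'   `q_pC`, `i_pA`, `normalized_q`; the baseline mean is kept as attribute
#'   `baseline_mean`.
#' @export
qeipsc_series <- function(sweeps, bin_sweeps = 100, stim_rate = 10,
                          baseline_min = 3) {
  n <- length(sweeps)
  n_bins <- n %/% bin_sweeps
  if (n_bins < 1L) stopf("fewer sweeps (%d) than one bin (%d)", n, bin_sweeps)
  if (n %% bin_sweeps != 0L)
    warnf("dropping incomplete final bin (%d sweeps)", n %% bin_sweeps)
  rows <- lapply(seq_len(n_bins), function(b) {
    idx <- ((b - 1L) * bin_sweeps + 1L):(b * bin_sweeps)
    m <- eipsc_measures(average_sweeps(sweeps[idx],
                                       ap_time = sweeps[[idx[1L]]]$stim_time))
    data.frame(bin = b, time_min = b * bin_sweeps / stim_rate / 60,
               q_pC = m$q, i_pA = m$i)
  })
  out <- do.call(rbind, rows)
  base <- mean(out$q_pC[out$time_min <= baseline_min + 1e-9])
  out$normalized_q <- out$q_pC / base
  structure(out, class = c("qeipsc_series", "data.frame"),
            baseline_mean = base)
}

#' Re-normalise a QeIPSC series by its baseline
#'
#' Idempotent: normalising an already-normalised series changes nothing.
#'
#' @param series a `qeipsc_series` data.frame.
#' @param baseline_min baseline duration in minutes.
#' @return the series with `normalized_q` recomputed.
#' @export
normalize_series <- function(series, baseline_min = 3) {
  base <- mean(series$normalized_q[series$time_min <= baseline_min + 1e-9])
  series$normalized_q <- series$normalized_q / base
  attr(series, "baseline_mean") <- attr(series, "baseline_mean") * base
  series
}

#' Default epoch sweep ranges for a drug-application protocol
#'
#' t1 = the last `epoch_sweeps` sweeps of the baseline, t2 = the last
#' `epoch_sweeps` sweeps of the drug application, t3 = the final
#' `epoch_sweeps` sweeps of the recording (washout).
#'
#' @param n_sweeps total sweeps available.
#' @param stim_rate Hz.
#' @param drug_onset_min,drug_end_min drug application bounds (min).
#' @param epoch_sweeps sweeps per epoch (default 1000 = 100 s at 10 Hz).
#' @return named list of integer index ranges `c(first, last)`.
#' @export
default_epochs <- function(n_sweeps, stim_rate = 10, drug_onset_min = 3,
                           drug_end_min = 8, epoch_sweeps = 1000) {
  i_on <- floor(drug_onset_min * 60 * stim_rate)
  i_end <- floor(drug_end_min * 60 * stim_rate)
  list(t1 = c(i_on - epoch_sweeps + 1L, i_on),
       t2 = c(i_end - epoch_sweeps + 1L, i_end),
       t3 = c(n_sweeps - epoch_sweeps + 1L, n_sweeps))
}

#' Epoch summaries and ratios for a pharmacology time course
#'
#' Builds one averaged eIPSC per epoch from consecutive sweeps and measures
#' its charge, peak, charge-to-peak ratio (the weighted decay time
#' constant), the relative amplitude of the second decay component
#' A2/(A1+A2) from a bi-exponential fit, and the slow charge integrated from
#' 36 ms after the eIPSC peak (when the fast component has fully decayed) to
#' the end of the inter-stimulus window. Ratios t2/t1 and t3/t1 are returned
#' for every metric.
#'
#' @param sweeps list of [sweep_record] from [segment_train()].
#' @param epochs named list of sweep index ranges (see [default_epochs()]);
#'   names become epoch labels, ranges must not overlap.
#' @param min_sweeps epochs smaller than this trigger a warning (default
#'   1000, the 100 s the protocol prescribes).
#' @return list of class `epoch_summary`: `epochs` (per-epoch data.frame
#'   with `q_pC`, `i_pA`, `q_over_i_ms`, `a2_fraction`, `slow36_pC`) and
#'   `ratios` (per-metric t2/t1 and t3/t1).
#' @export
epoch_summary <- function(sweeps, epochs, min_sweeps = 1000) {
  labs <- names(epochs)
  if (is.null(labs) || any(labs == "")) stopf("epochs must be named")
  rng <- do.call(rbind, lapply(epochs, function(e) sort(e)))
  ord <- order(rng[, 1L])
  if (any(rng[ord, 1L][-1L] <= rng[ord, 2L][-nrow(rng)]))
    stopf("epochs overlap")
  dur <- sweep_duration_ms(sweeps[[1L]])
  rows <- lapply(seq_along(epochs), function(k) {
    e <- epochs[[k]]
    if (e[1L] < 1L || e[2L] > length(sweeps)) stopf("epoch outside recording")
    n_e <- e[2L] - e[1L] + 1L
    if (n_e < min_sweeps)
      warnf("epoch %s has %d sweeps (< %d)", labs[k], n_e, min_sweeps)
    avg <- average_sweeps(sweeps[e[1L]:e[2L]],
                          ap_time = sweeps[[e[1L]]]$stim_time)
    m <- eipsc_measures(avg)
    fit <- fit_biexponential(avg, m$peak_time + 0.5, dur)
    s36 <- slow_charge(avg, avg$stim_time, horizon = c(avg$stim_time, dur),
                       peak_time = m$peak_time)
    data.frame(epoch = labs[k], n_sweeps = n_e, q_pC = m$q, i_pA = m$i,
               q_over_i_ms = weighted_tau(m$q, m$i),
               a2_fraction = if (fit$converged) fit$a2_fraction else NA_real_,
               slow36_pC = s36, stringsAsFactors = FALSE)
  })
  ep <- do.call(rbind, rows)
  ratio_of <- function(metric, num, den) {
    v <- ep[[metric]]
    v[ep$epoch == num] / v[ep$epoch == den]
  }
  mets <- c("q_pC", "i_pA", "q_over_i_ms", "a2_fraction", "slow36_pC")
  ratios <- do.call(rbind, lapply(mets, function(mm) {
    data.frame(metric = mm,
               t2_over_t1 = if (all(c("t1", "t2") %in% ep$epoch))
                 ratio_of(mm, "t2", "t1") else NA_real_,
               t3_over_t1 = if (all(c("t1", "t3") %in% ep$epoch))
                 ratio_of(mm, "t3", "t1") else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(epochs = ep, ratios = ratios), class = "epoch_summary")
}

#' Percent reduction implied by an epoch ratio
#'
#' @param ratio epoch ratio (e.g. t2/t1).
#' @return percent reduction, `100 * (1 - ratio)`.
#' @export
percent_reduction <- function(ratio) 100 * (1 - ratio)

#' Contrast epoch ratios between two condition groups
#'
#' For each epoch ratio, reports group means, the relative difference of the
#' means `100 * (mean_A - mean_B) / mean_A` (how much larger the reduction
#' is in group B than in group A) and a two-sided Mann-Whitney p-value.
#'
#' @param group_a,group_b data.frames with one row per cell and columns
#'   `t2_over_t1` and/or `t3_over_t1` (e.g. stacked from
#'   [epoch_summary()] ratios of the charge metric).
#' @return data.frame: `epoch_ratio`, `mean_a`, `mean_b`, `n_a`, `n_b`,
#'   `rel_diff_pct`, `p_value`.
#' @export
condition_contrast <- function(group_a, group_b) {
  if (nrow(group_a) < 2 || nrow(group_b) < 2) stopf("need >= 2 cells per group")
  cols <- intersect(c("t2_over_t1", "t3_over_t1"),
                    intersect(names(group_a), names(group_b)))
  if (!length(cols)) stopf("no shared ratio columns")
  do.call(rbind, lapply(cols, function(cc) {
    a <- group_a[[cc]][is.finite(group_a[[cc]])]
    b <- group_b[[cc]][is.finite(group_b[[cc]])]
    p <- if (length(a) >= 3 && length(b) >= 3)
      group_compare(a, b)$p_value else NA_real_
    data.frame(epoch_ratio = cc, mean_a = mean(a), mean_b = mean(b),
               n_a = length(a), n_b = length(b),
               rel_diff_pct = 100 * (mean(a) - mean(b)) / mean(a),
               p_value = p, stringsAsFactors = FALSE)
  }))
}
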