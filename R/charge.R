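#' Per-trial charge, peak and synaptic-delay metrics
#'
#' The trial charge is the 5-ms time integral of the current starting 1 ms
#' after the presynaptic spike, after zeroing the mean current over the 10 ms
#' preceding that window. Reported sign convention: IPSCs (inward, negative
#' raw current) give *positive* charge; the baseline null is centred on zero
#' and outward noise excursions give negative charge.
#'
#' @param sweep a [sweep_record].
#' @param ap_time presynaptic spike time in ms (defaults to the sweep's own
#'   annotation).
#' @return charge in pC (1 pA·ms = 0.001 pC).
#' @export
trial_charge <- function(sweep, ap_time = sweep$ap_time) {
  fs <- sweep$sampling_rate
  if (is.na(ap_time)) stopf("trial_charge requires an AP time")
  t0 <- ap_time + 1
  t1 <- ap_time + 6
  if (t0 - 10 < 0 || t1 > sweep_duration_ms(sweep))
    stopf("charge window [%.1f, %.1f) ms (plus 10 ms baseline) out of range",
          t0, t1)
  ib0 <- ms_to_index(t0 - 10, fs)
  ib1 <- ms_to_index(t0, fs) - 1L
  base <- mean(sweep$samples[ib0:ib1])
  i0 <- ms_to_index(t0, fs)
  i1 <- ms_to_index(t1, fs)
  -trapz(sweep$samples[i0:i1] - base, 1000 / fs) / 1000
}

#' Null distribution of trial charges sampled from the pre-stimulus baseline
#'
#' Draws anchor times uniformly inside the pre-stimulus region of randomly
#' chosen sweeps and measures [trial_charge()] at each anchor as if a spike
#' had occurred there. On stationary noise this distribution is narrow and
#' symmetric about zero; it is the reference null for connectivity
#' classification and underlies the symmetric-failure assumption of the
#' failure-rate estimator.
#'
#' @param sweeps list of [sweep_record] objects.
#' @param n_draws number of anchors to draw.
#' @param seed optional integer seed (local to this call).
#' @return numeric vector of `n_draws` charges in pC.
#' @export
baseline_charge_distribution <- function(sweeps, n_draws = 1000, seed = NULL) {
  if (inherits(sweeps, "sweep_record")) sweeps <- list(sweeps)
  stim <- sweeps[[1L]]$stim_time
  if (stim < 16) stopf("need >= 16 ms of pre-stimulus baseline (have %.1f)", stim)
  with_seed(seed, {
    sel <- sample.int(length(sweeps), n_draws, replace = TRUE)
    anchors <- stats::runif(n_draws, 9, stim - 6)
    vapply(seq_len(n_draws),
           function(i) trial_charge(sweeps[[sel[i]]], anchors[i]), 0)
  })
}

#' Peak amplitude and synaptic delay of a trial or averaged trace
#'
#' The peak is the maximum of the sign-inverted, baseline-zeroed current in
#' the search window (default 10 ms after the spike). The argmax is located
#' on a lightly smoothed copy (0.25 ms boxcar) for stability; the amplitude
#' is read from the unsmoothed trace at that index. The synaptic delay is the
#' peak-to-peak time between the presynaptic AP and the IPSC peak. Trials
#' whose peak does not exceed twice the baseline noise SD are flagged
#' undetermined.
#'
#' @param sweep a [sweep_record].
#' @param ap_time spike time in ms.
#' @param search [time_window]; default `[ap_time, ap_time + 10)`.
#' @return list with `peak_amp` (pA, positive), `peak_time` (ms), `delay`
#'   (ms) and `undetermined` (logical).
#' @export
peak_and_delay <- function(sweep, ap_time = sweep$ap_time, search = NULL) {
  fs <- sweep$sampling_rate
  if (is.na(ap_time)) stopf("peak_and_delay requires an AP time")
  search <- if (is.null(search))
    time_window(ap_time, min(ap_time + 10, sweep_duration_ms(sweep)))
  else as_time_window(search)
  ib0 <- max(1L, ms_to_index(ap_time - 10, fs))
  ib1 <- max(ib0 + 1L, ms_to_index(ap_time, fs) - 1L)
  base <- mean(sweep$samples[ib0:ib1])
  y <- -(sweep$samples - base)                     # reported-positive
  noise_sd <- stats::sd(y[ib0:ib1])
  i0 <- ms_to_index(search$start, fs)
  i1 <- min(length(y), ms_to_index(search$end, fs) - 1L)
  if (i1 <= i0) stopf("empty search window")
  ys <- boxcar(y, round(0.25 * fs / 1000))
  ipk <- i0 - 1L + which.max(ys[i0:i1])
  peak_amp <- y[ipk]
  peak_time <- index_to_ms(ipk, fs)
  list(peak_amp = peak_amp, peak_time = peak_time,
       delay = peak_time - ap_time,
       undetermined = is.finite(noise_sd) && peak_amp < 2 * noise_sd)
}

#' Slow spillover charge of an averaged trace by direct tail integration
#'
#' Integrates the baseline-zeroed, sign-inverted current from 36 ms after the
#' IPSC peak (when the fast bi-exponential component has fully decayed) to
#' the end of the horizon. This is the "tail36" measure of the slow charge
#' carried by high-affinity extrasynaptic GABA-A receptors; see
#' [fit_slow_component()] for the cumulative-charge fit alternative.
#'
#' @param sweep averaged [sweep_record].
#' @param ap_time spike time in ms; for AP-failure averages pass the mean
#'   spike time of the pair so the integration window is comparable.
#' @param horizon [time_window] for the integration end; default from
#'   `ap_time` to `min(ap_time + 2000, sweep end)`.
#' @param peak_time IPSC peak time in ms; located automatically when `NULL`.
#' @param baseline_ms local baseline length before `ap_time` (default 10 ms;
#'   longer baselines reduce the integrated offset error of long horizons
#'   when enough pre-stimulus recording is available).
#' @return charge in pC.
#' @export
slow_charge <- function(sweep, ap_time = sweep$ap_time, horizon = NULL,
                        peak_time = NULL, baseline_ms = 10) {
  fs <- sweep$sampling_rate
  dur <- sweep_duration_ms(sweep)
  horizon <- if (is.null(horizon)) time_window(ap_time, min(ap_time + 2000, dur))
  else as_time_window(horizon)
  if (horizon$end > dur + 1e-9) stopf("horizon extends beyond the sweep")
  if (is.null(peak_time))
    peak_time <- peak_and_delay(sweep, ap_time)$peak_time
  t0 <- peak_time + 36
  if (t0 >= horizon$end) stopf("no samples beyond peak + 36 ms in horizon")
  ib0 <- max(1L, ms_to_index(ap_time - baseline_ms, fs))
  ib1 <- max(ib0 + 1L, ms_to_index(ap_time, fs) - 1L)
  base <- mean(sweep$samples[ib0:ib1])
  i0 <- ms_to_index(t0, fs)
  i1 <- min(length(sweep$samples), ms_to_index(horizon$end, fs))
  -trapz(sweep$samples[i0:i1] - base, 1000 / fs) / 1000
}

#' Pointwise mean trace over a set of sweeps
#'
#' @param sweeps list of [sweep_record] objects of equal length.
#' @param ap_time AP annotation to attach to the averaged sweep (typically
#'   the mean spike time of the contributing trials).
#' @return a [sweep_record] holding the mean trace.
#' @export
average_sweeps <- function(sweeps, ap_time = NA_real_) {
  if (!length(sweeps)) stopf("cannot average zero sweeps")
  m <- rowMeans(vapply(sweeps, function(s) s$samples,
                       numeric(length(sweeps[[1L]]$samples))))
  sweep_record(m, sweeps[[1L]]$sampling_rate, sweeps[[1L]]$stim_time,
               ap_time = ap_time)
}

#' Per-trial metrics table for one pair
#'
#' Applies [trial_charge()] and [peak_and_delay()] to every sweep with a
#' presynaptic AP annotation.
#'
#' @param pair a [pair_recording].
#' @return data.frame with one row per trial: `trial`, `ap_success`,
#'   `ap_time`, `q_fast_pC`, `peak_pA`, `peak_time_ms`, `delay_ms`,
#'   `peak_undetermined`.
#' @export
trial_metrics <- function(pair) {
  rows <- lapply(seq_along(pair$sweeps), function(i) {
    sw <- pair$sweeps[[i]]
    if (is.na(sw$ap_time)) {
      data.frame(trial = i, ap_success = FALSE, ap_time = NA_real_,
                 q_fast_pC = NA_real_, peak_pA = NA_real_,
                 peak_time_ms = NA_real_, delay_ms = NA_real_,
                 peak_undetermined = NA)
    } else {
      pk <- peak_and_delay(sw)
      data.frame(trial = i, ap_success = TRUE, ap_time = sw$ap_time,
                 q_fast_pC = trial_charge(sw), peak_pA = pk$peak_amp,
                 peak_time_ms = pk$peak_time, delay_ms = pk$delay,
                 peak_undetermined = pk$undetermined)
    }
  })
  do.call(rbind, rows)
}
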