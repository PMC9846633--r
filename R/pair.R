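#' Full trial-level analysis of one pair recording
#'
#' Runs the complete per-pair chain: per-trial charge/peak/delay metrics,
#' baseline charge null, Kolmogorov-Smirnov connectivity classification,
#' failure-rate estimation from the symmetric null, sliding-difference
#' phasic/delayed classification of successes, bi-/mono-exponential decay
#' fits of the class-averaged traces, and slow spillover charge estimation
#' per trial class. AP-success averages include postsynaptic failures but
#' exclude presynaptic stimulation failures.
#'
#' @param pair a [pair_recording].
#' @param alpha significance level for connectivity (default 0.05).
#' @param n_baseline_draws anchors for the baseline null; default
#'   `max(1000, n_trials)`.
#' @param slow_mode `"auto"` (cumulative fit when >= 1 s of post-peak
#'   recording is available, tail integration otherwise), `"cumsum"` or
#'   `"tail36"`.
#' @param min_delayed minimum delayed trials for a mono-exponential fit.
#' @param fit_ms length of the fast-decay fit window after the peak (ms).
#' @param seed seed for the baseline-null draws (local).
#' @return object of class `pair_analysis`: `trials` (per-trial metrics and
#'   labels), `connectivity`, `failure`, `fast_rise`, `fits` (named list of
#'   [fit_biexponential()]/[fit_monoexponential()]/[fit_slow_component()]
#'   results) and `summary` (one-row data.frame, see [pair_summary()]).
#' @export
analyze_pair <- function(pair, alpha = 0.05, n_baseline_draws = NULL,
                         slow_mode = c("auto", "cumsum", "tail36"),
                         min_delayed = 5, fit_ms = 80, seed = NULL) {
  slow_mode <- match.arg(slow_mode)
  tm <- trial_metrics(pair)
  tm$ipsc_success <- NA
  tm$event_class <- ifelse(tm$ap_success, "undetermined", "undetermined")
  ap_idx <- which(tm$ap_success)
  n_ap <- length(ap_idx)
  dur <- sweep_duration_ms(pair$sweeps[[1L]])

  note <- character(0)
  nd <- n_baseline_draws %||% max(1000L, length(pair$sweeps))
  baseline <- baseline_charge_distribution(pair$sweeps, nd, seed = seed)
  conn <- if (n_ap >= 10)
    classify_connectivity(tm$q_fast_pC[ap_idx], baseline, alpha,
                          pair_id = pair$pair_id)
  else {
    note <- c(note, "fewer than 10 AP trials: connectivity undetermined")
    NULL
  }
  connected <- if (is.null(conn)) NA else conn$connected

  fail <- NULL
  frt <- NULL
  cls <- NULL
  if (isTRUE(connected)) {
    fail <- failure_rate(tm$q_fast_pC[ap_idx])
    tm$ipsc_success[ap_idx] <- TRUE
    tm$ipsc_success[ap_idx[fail$failure_trials]] <- FALSE
    tm$event_class[ap_idx[fail$failure_trials]] <- "failure"
    succ_idx <- ap_idx[setdiff(seq_len(n_ap), fail$failure_trials)]
    if (length(succ_idx) >= 3) {
      mean_succ <- average_sweeps(pair$sweeps[succ_idx],
                                  ap_time = mean(tm$ap_time[succ_idx]))
      frt <- fast_rise_time(mean_succ)
      if (!is.na(frt$time)) {
        cls <- classify_phasic_delayed(pair$sweeps[succ_idx], frt)
        tm$event_class[succ_idx] <- cls$event_class
      } else {
        note <- c(note, "flat success average: classes undetermined")
      }
      if (frt$undetermined)
        note <- c(note, "no detectable fast component on the mean trace")
    }
  } else if (identical(connected, FALSE)) {
    tm$ipsc_success[ap_idx] <- FALSE
    tm$event_class[ap_idx] <- "failure"
  }

  fits <- list()
  mean_ap_time <- mean(tm$ap_time[ap_idx])
  I_AP_pos <- Q_AP_pos <- wtau <- delay_ms <- NA_real_
  TAU1 <- TAU2 <- a2f <- NA_real_
  if (n_ap >= 3) {
    mean_ap <- average_sweeps(pair$sweeps[ap_idx], ap_time = mean_ap_time)
    pk <- peak_and_delay(mean_ap)
    I_AP_pos <- pk$peak_amp
    delay_ms <- pk$delay
    # fast-decay fits start 0.5 ms past the peak: the first half-millisecond
    # is still flattened by the rise and biases both time constants upward
    t_end <- min(pk$peak_time + 0.5 + fit_ms, dur)
    fits$ap_pos <- fit_biexponential(mean_ap, pk$peak_time + 0.5, t_end)
    if (fits$ap_pos$converged) {
      TAU1 <- fits$ap_pos$TAU1; TAU2 <- fits$ap_pos$TAU2
      a2f <- fits$ap_pos$a2_fraction
      Q_AP_pos <- fits$ap_pos$q_fit
      if (I_AP_pos > 0) wtau <- weighted_tau(Q_AP_pos, I_AP_pos)
    }
    mode <- if (slow_mode == "auto") {
      if (dur - pk$peak_time >= 1036) "cumsum" else "tail36"
    } else slow_mode
    fits$slow_ap_pos <- suppressWarnings(
      fit_slow_component(mean_ap, mean_ap_time, mode = mode))
  }

  I_phasic <- TAU2_phasic <- Q2_phasic <- NA_real_
  ph_idx <- which(tm$event_class == "phasic")
  if (length(ph_idx) >= 3) {
    mean_ph <- average_sweeps(pair$sweeps[ph_idx],
                              ap_time = mean(tm$ap_time[ph_idx]))
    pkp <- peak_and_delay(mean_ph)
    I_phasic <- pkp$peak_amp
    fits$phasic <- fit_biexponential(mean_ph, pkp$peak_time + 0.5,
                                     min(pkp$peak_time + 0.5 + fit_ms, dur))
    if (fits$phasic$converged) {
      TAU2_phasic <- fits$phasic$TAU2
      Q2_phasic <- fits$phasic$A2 * fits$phasic$TAU2 / 1000
    }
  }

  Q_delayed <- TAU_delayed <- NA_real_
  de_idx <- which(tm$event_class == "delayed")
  # delayed events rise slowly; start the decay fit 3 ms past the peak so
  # the residual rise does not flatten the early decay
  fits$delayed <- if (length(de_idx) >= 1) {
    mean_de <- average_sweeps(pair$sweeps[de_idx],
                              ap_time = mean(tm$ap_time[de_idx]))
    pkd <- peak_and_delay(mean_de)
    fit_monoexponential(mean_de, pkd$peak_time + 3,
                        min(pkd$peak_time + 53, dur),
                        n_events = length(de_idx), min_events = min_delayed)
  } else NULL
  if (!is.null(fits$delayed) && fits$delayed$converged) {
    Q_delayed <- fits$delayed$q_fit
    TAU_delayed <- fits$delayed$TAU1
  } else if (length(de_idx) > 0 && length(de_idx) < min_delayed) {
    note <- c(note, sprintf("only %d delayed IPSCs: not fitted", length(de_idx)))
  }

  Q_slow_ipsc_fail <- Q_slow_ap_neg <- NA_real_
  fa_idx <- which(tm$ap_success & tm$ipsc_success %in% FALSE)
  if (length(fa_idx) >= 3) {
    mean_fa <- average_sweeps(pair$sweeps[fa_idx],
                              ap_time = mean(tm$ap_time[fa_idx]))
    Q_slow_ipsc_fail <- slow_charge(mean_fa)
  }
  no_idx <- which(!tm$ap_success)
  if (length(no_idx) >= 3 && is.finite(mean_ap_time)) {
    mean_no <- average_sweeps(pair$sweeps[no_idx], ap_time = mean_ap_time)
    # AP-failure trials have no spike; integrate the same window as AP trials
    pk_ref <- mean_ap_time + if (is.finite(delay_ms)) delay_ms else 1.5
    Q_slow_ap_neg <- slow_charge(mean_no, mean_ap_time, peak_time = pk_ref)
  }

  n_succ <- sum(tm$ipsc_success %in% TRUE)
  summary <- data.frame(
    pair_id = pair$pair_id, phenotype = pair$phenotype,
    n_trials = nrow(tm), n_ap = n_ap, connected = connected,
    ks_p = if (is.null(conn)) NA_real_ else conn$ks_p,
    p_fail = if (is.null(fail)) NA_real_ else fail$p_fail,
    I_AP_pos = I_AP_pos, Q_AP_pos = Q_AP_pos,
    TAU1 = TAU1, TAU2 = TAU2, a2_fraction = a2f,
    weighted_tau_ms = wtau, delay_ms = delay_ms,
    I_phasic = I_phasic, TAU2_phasic = TAU2_phasic, Q2_phasic = Q2_phasic,
    Q_delayed = Q_delayed, TAU_delayed = TAU_delayed,
    q_delayed_over_i_phasic_ms =
      if (is.finite(Q_delayed) && is.finite(I_phasic) && I_phasic > 0)
        weighted_tau(Q_delayed, I_phasic) else NA_real_,
    Q_slow_ap_pos = if (!is.null(fits$slow_ap_pos))
      fits$slow_ap_pos$q_slow else NA_real_,
    tau_slow = if (!is.null(fits$slow_ap_pos))
      fits$slow_ap_pos$tau_slow else NA_real_,
    Q_slow_ipsc_fail = Q_slow_ipsc_fail, Q_slow_ap_neg = Q_slow_ap_neg,
    delayed_fraction = if (n_succ > 0)
      sum(tm$event_class == "delayed") / n_succ else NA_real_,
    stringsAsFactors = FALSE)

  structure(list(trials = tm, connectivity = conn, failure = fail,
                 fast_rise = frt, event_classes = cls, fits = fits,
                 summary = summary, notes = note),
            class = "pair_analysis")
}

#' @export
print.pair_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<pair_analysis> %s [%s]: connected = %s, p_fail = %s,\n",
                     "  I_AP(+) = %.1f pA, Q_AP(+) = %.3f pC, ",
                     "weighted tau = %.2f ms, Q_slow = %.3f pC\n"),
              s$pair_id, s$phenotype, as.character(s$connected),
              format(s$p_fail, digits = 3), s$I_AP_pos, s$Q_AP_pos,
              s$weighted_tau_ms, s$Q_slow_ap_pos))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' One-row summary of a pair analysis
#'
#' Column names follow the field's symbols: `I_AP_pos` and `Q_AP_pos` (peak
#' and fitted charge of the mean AP-success trace), `TAU1`/`TAU2` and
#' `a2_fraction` from the bi-exponential decay, `weighted_tau_ms`
#' (= 1000*Q_AP_pos/I_AP_pos), `delay_ms` (AP peak to IPSC peak),
#' `I_phasic`, `TAU2_phasic`, `Q2_phasic`, `Q_delayed`, `TAU_delayed`,
#' `q_delayed_over_i_phasic_ms`, `Q_slow_ap_pos`/`tau_slow`,
#' `Q_slow_ipsc_fail`, `Q_slow_ap_neg`, `p_fail` and `delayed_fraction`.
#'
#' @param x a [pair_recording] or the result of [analyze_pair()].
#' @param ... passed on to [analyze_pair()] when `x` is a recording.
#' @return a one-row data.frame.
#' @export
pair_summary <- function(x, ...) {
  if (inherits(x, "pair_recording")) x <- analyze_pair(x, ...)
  stopifnot(inherits(x, "pair_analysis"))
  x$summary
}
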