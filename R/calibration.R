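# Calibration experiments: simulation studies that measure the operating
# characteristics of every estimator and classifier in the package under
# the study conditions the generator encodes. These back the validation
# suite and the reproduction script; sizes are parameters so callers choose
# their precision/runtime trade-off.

#' Parameter-recovery experiment for the exponential decompositions
#'
#' Simulates connected pairs at recording-like SNR and refits the kinetic
#' parameters from the averaged traces: `TAU1`, `TAU2` and the fitted charge
#' from phasic-event averages, `TAU_delayed` from delayed-event averages
#' (separate delayed-dominated simulations) and `tau_slow`/`q_slow` from the
#' cumulative-charge fit on long sweeps.
#'
#' @param n_pairs pairs per condition.
#' @param n_trials trials per pair.
#' @param noise_sd recording noise in pA.
#' @param sampling_rate Hz.
#' @param seed integer seed.
#' @return data.frame with one row per pair and parameter: `parameter`,
#'   `true`, `estimate`, `rel_error`.
#' @export
recovery_experiment <- function(n_pairs = 100, n_trials = 60, noise_sd = 5,
                                sampling_rate = 10000, seed = 1) {
  rows <- list()
  add <- function(par, true, est) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = par, true = true, estimate = est,
      rel_error = abs(est - true) / abs(true))
  }
  for (r in seq_len(n_pairs)) {
    # phasic kinetics + slow component: long sweeps, no delayed events
    sim <- simulate_pair(synth_pair_config(
      n_trials = n_trials, p_ap = 1, p_fail = 0, p_delayed = 0,
      noise_sd = noise_sd, sweep_ms = 2100, pre_ms = 50,
      sampling_rate = sampling_rate, seed = seed + 7L * r))
    tr <- sim$truth$trials
    avg <- average_sweeps(sim$pair$sweeps, ap_time = mean(tr$ap_time))
    pk <- peak_and_delay(avg)
    fit <- fit_biexponential(avg, pk$peak_time + 0.5, pk$peak_time + 100.5)
    pp <- sim$truth$phasic_params
    if (fit$converged && fit$model == "biexp") {
      add("TAU1", pp$TAU1, fit$TAU1)
      add("TAU2", pp$TAU2, fit$TAU2)
      # the decay fit estimates the waveform charge beyond its fit start;
      # quadrature of the true waveform past peak + 0.5 ms is the oracle
      tg <- seq(0, 600, by = 0.01)
      w <- -phasic_waveform(tg, pp)
      tpk <- tg[which.max(w)]
      sel <- tg >= tpk + 0.5
      add("Q_AP_pos", trapz(w[sel], 0.01) / 1000, fit$q_fit)
    }
    slow <- fit_slow_component(avg, avg$ap_time, mode = "cumsum")
    sp <- sim$truth$spillover_params
    if (slow$converged) {
      add("tau_slow", sp$tau_slow, slow$tau_slow)
      add("q_slow", sp$q_slow, slow$q_slow)
    }
    # delayed kinetics: delayed-only pair, short sweeps, more averaging
    # (delayed events are small, ~12 pA, so single pairs pool more trials)
    n_del <- max(80L, n_trials)
    simd <- simulate_pair(synth_pair_config(
      n_trials = n_del, p_ap = 1, p_fail = 0, p_delayed = 1,
      noise_sd = noise_sd, sweep_ms = 250, pre_ms = 50,
      sampling_rate = sampling_rate, seed = seed + 7L * r + 3L))
    avgd <- average_sweeps(simd$pair$sweeps,
                           ap_time = mean(simd$truth$trials$ap_time))
    pkd <- peak_and_delay(avgd)
    fd <- fit_monoexponential(avgd, pkd$peak_time + 3, pkd$peak_time + 53,
                              n_events = n_del)
    if (fd$converged) add("TAU_delayed", simd$truth$delayed_params$TAU,
                          fd$TAU1)
  }
  do.call(rbind, rows)
}

#' Failure-rate estimator calibration
#'
#' Simulates trial-charge samples with a symmetric zero-centred failure
#' distribution and well-separated successes (the regime the estimator
#' assumes) and measures the bias of [failure_rate()].
#'
#' @param p_true true failure probabilities to probe.
#' @param n_trials trials per replicate.
#' @param n_reps replicates per probability.
#' @param separation_sd success-failure separation in charge-noise SDs.
#' @param seed integer seed.
#' @return data.frame: `p_true`, `mean_estimate`, `bias`, `mean_abs_bias`.
#' @export
failure_calibration <- function(p_true = c(0.1, 0.3, 0.5), n_trials = 200,
                                n_reps = 500, separation_sd = 5, seed = 1) {
  with_seed(seed, {
    do.call(rbind, lapply(p_true, function(pf) {
      est <- replicate(n_reps, {
        fail <- stats::runif(n_trials) < pf
        q <- ifelse(fail, stats::rnorm(n_trials, 0, 0.02),
                    stats::rnorm(n_trials, 0.02 * separation_sd, 0.02))
        failure_rate(q)$p_fail
      })
      data.frame(p_true = pf, mean_estimate = mean(est),
                 bias = mean(est) - pf, mean_abs_bias = abs(mean(est) - pf))
    }))
  })
}

#' Connectivity-classifier calibration
#'
#' Simulates unconnected (null) pairs through the generator and measures the
#' size of the reported KS test (`ks_p < alpha`) and the full classifier's
#' false-positive rate; power is measured on connected pairs whose mean
#' charge shift is `shift_sd` baseline SDs.
#'
#' @param n_null null pairs.
#' @param n_power connected replicates for the power estimate.
#' @param n_trials AP trials per pair.
#' @param alpha significance level.
#' @param shift_sd mean shift (in baseline charge SDs) for the power runs.
#' @param n_baseline_draws baseline anchors per pair. Pairs are simulated
#'   with a 150-ms pre-stimulus baseline so the default 1000 anchors are
#'   quasi-independent; short baselines make overlapping anchors dependent
#'   and distort the size of the KS test.
#' @param seed integer seed.
#' @return list: `type1_ks`, `false_positive_rate`, `power`, `alpha`, sizes.
#' @export
connectivity_calibration <- function(n_null = 1000, n_power = 200,
                                     n_trials = 50, alpha = 0.05,
                                     shift_sd = 3, n_baseline_draws = 1000,
                                     seed = 1) {
  with_seed(seed, {
    null_one <- function(r) {
      sim <- simulate_pair(synth_pair_config(
        connected = FALSE, n_trials = n_trials, p_ap = 1, noise_sd = 5,
        spillover_params = list(q_slow = 0, tau_slow = 359, rise_tau = 5,
                                fail_fraction = 1 / 3,
                                unconnected_fraction = 0),
        sweep_ms = 175, pre_ms = 150, sampling_rate = 10000,
        seed = sample.int(.Machine$integer.max, 1)))
      q <- vapply(sim$pair$sweeps, trial_charge, 0)
      bl <- baseline_charge_distribution(sim$pair$sweeps, n_baseline_draws)
      r <- classify_connectivity(q, bl, alpha)
      c(ks = r$ks_p < alpha, fp = r$connected)
    }
    nulls <- vapply(seq_len(n_null), null_one, c(ks = TRUE, fp = TRUE))
    # power: shift the charges by shift_sd baseline SDs
    pow <- vapply(seq_len(n_power), function(r) {
      sim <- simulate_pair(synth_pair_config(
        connected = FALSE, n_trials = n_trials, p_ap = 1, noise_sd = 5,
        spillover_params = list(q_slow = 0, tau_slow = 359, rise_tau = 5,
                                fail_fraction = 1 / 3,
                                unconnected_fraction = 0),
        sweep_ms = 175, pre_ms = 150, sampling_rate = 10000,
        seed = sample.int(.Machine$integer.max, 1)))
      q <- vapply(sim$pair$sweeps, trial_charge, 0)
      bl <- baseline_charge_distribution(sim$pair$sweeps, n_baseline_draws)
      res <- classify_connectivity(q + shift_sd * stats::sd(bl), bl, alpha)
      res$connected && res$ks_p < 1e-4
    }, TRUE)
    list(type1_ks = mean(nulls["ks", ]),
         false_positive_rate = mean(nulls["fp", ]),
         power = mean(pow), alpha = alpha,
         n_null = n_null, n_power = n_power)
  })
}

#' Phasic/delayed classifier accuracy against ground truth
#'
#' Simulates connected pairs with known event classes at the requested
#' signal-to-noise ratio and scores [classify_phasic_delayed()] (using the
#' pair's own [fast_rise_time()]) against the generator labels.
#'
#' @param n_events minimum number of labelled success events.
#' @param snr peak amplitude over noise SD.
#' @param p_delayed delayed prevalence among successes.
#' @param trials_per_pair trials per simulated pair.
#' @param seed integer seed.
#' @return list: `accuracy`, `n_events`, `confusion` (2x2 table).
#' @export
classifier_calibration <- function(n_events = 1000, snr = 8,
                                   p_delayed = 0.25, trials_per_pair = 100,
                                   seed = 1) {
  peak <- 55
  cm <- matrix(0, 2, 2,
               dimnames = list(estimate = c("phasic", "delayed"),
                               truth = c("phasic", "delayed")))
  r <- 0L
  with_seed(seed, {
    while (sum(cm) < n_events) {
      r <- r + 1L
      sim <- simulate_pair(synth_pair_config(
        n_trials = trials_per_pair, p_ap = 1, p_fail = 0,
        p_delayed = p_delayed, noise_sd = peak / snr,
        sweep_ms = 160, pre_ms = 50,
        seed = sample.int(.Machine$integer.max, 1)))
      truth <- sim$truth$trials$event_class
      succ <- which(truth %in% c("phasic", "delayed"))
      avg <- average_sweeps(sim$pair$sweeps[succ],
                            ap_time = mean(sim$truth$trials$ap_time[succ]))
      frt <- fast_rise_time(avg)
      if (is.na(frt$time)) next
      cls <- classify_phasic_delayed(sim$pair$sweeps[succ], frt)
      for (k in seq_along(succ))
        cm[cls$event_class[k], truth[succ[k]]] <-
          cm[cls$event_class[k], truth[succ[k]]] + 1
    }
  })
  list(accuracy = sum(diag(cm)) / sum(cm), n_events = sum(cm),
       confusion = cm)
}

#' Spillover charge ordering across trial classes
#'
#' Simulates connected pairs and measures the slow charge of the mean trace
#' of each trial class (using the generator's true labels, to probe the
#' charge measurement rather than the upstream classifiers): successes
#' should carry the full spillover, postsynaptic failures about a third,
#' and AP failures none.
#'
#' @param n_reps replicate pairs.
#' @param n_trials trials per pair.
#' @param seed integer seed.
#' @return list: `ordering_rate` (fraction of replicates with
#'   Q_slow(AP+) > Q_slow(AP+,IPSC-) > Q_slow(AP-)), `ap_neg_mean`,
#'   `ap_neg_sem`, and the per-replicate data.frame `draws`.
#' @export
spillover_experiment <- function(n_reps = 100, n_trials = 100, seed = 1) {
  with_seed(seed, {
    draws <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
      sim <- simulate_pair(synth_pair_config(
        n_trials = n_trials, p_ap = 0.62, p_fail = 0.35, p_delayed = 0.25,
        noise_sd = 5, sweep_ms = 500, pre_ms = 50, sampling_rate = 10000,
        seed = sample.int(.Machine$integer.max, 1)))
      tr <- sim$truth$trials
      mean_ap <- mean(tr$ap_time, na.rm = TRUE)
      q_of <- function(idx) {
        if (length(idx) < 3) return(NA_real_)
        avg <- average_sweeps(sim$pair$sweeps[idx], ap_time = mean_ap)
        slow_charge(avg, mean_ap, peak_time = mean_ap + 1.5, baseline_ms = 30)
      }
      data.frame(
        q_ap_pos = q_of(which(tr$ap & tr$ipsc %in% TRUE)),
        q_ipsc_fail = q_of(which(tr$ap & tr$ipsc %in% FALSE)),
        q_ap_neg = q_of(which(!tr$ap)))
    }))
    ok <- stats::complete.cases(draws)
    ordering <- draws$q_ap_pos > draws$q_ipsc_fail &
      draws$q_ipsc_fail > draws$q_ap_neg
    list(ordering_rate = mean(ordering[ok]),
         ap_neg_mean = mean(draws$q_ap_neg, na.rm = TRUE),
         ap_neg_sem = stats::sd(draws$q_ap_neg, na.rm = TRUE) /
           sqrt(sum(is.finite(draws$q_ap_neg))),
         draws = draws)
  })
}

#' Type-I error calibration of the population tests
#'
#' Draws null replicates (both groups from one normal distribution) and
#' reports the empirical rejection rate at `alpha` for the Mann-Whitney
#' comparison, the Conover squared-ranks variance test and the Spearman
#' correlation.
#'
#' @param n_reps replicates per test.
#' @param alpha level.
#' @param n1,n2 group sizes for the two-sample tests.
#' @param n_corr sample size for the correlation test.
#' @param seed integer seed.
#' @return named list of rejection rates.
#' @export
stats_calibration <- function(n_reps = 2000, alpha = 0.05, n1 = 12, n2 = 15,
                              n_corr = 30, seed = 1) {
  with_seed(seed, {
    mw <- mean(replicate(n_reps,
      group_compare(stats::rnorm(n1), stats::rnorm(n2))$p_value < alpha))
    cv <- mean(replicate(n_reps,
      conover_variance_test(stats::rnorm(n1),
                            stats::rnorm(n2))$p_value < alpha))
    sp <- mean(replicate(n_reps,
      spearman_corr(stats::rnorm(n_corr),
                    stats::rnorm(n_corr))$p_value < alpha))
    list(mann_whitney = mw, conover = cv, spearman = sp)
  })
}

#' Bootstrap bimodality test: detection and self-draw calibration
#'
#' Detection: a clearly bimodal observed sample (two tight clusters) tested
#' against a unimodal uniform reference; reports the fraction of seeded runs
#' with p < 0.05. Self-calibration: the observed sample itself is a draw
#' from the reference; reports the rejection rate at 0.05, which should not
#' exceed the nominal level by much.
#'
#' @param n_runs detection runs.
#' @param n_outer self-calibration outer replicates.
#' @param n_reps bootstrap replicates per test.
#' @param seed integer seed.
#' @return list: `detect_rate`, `self_rejection_rate`.
#' @export
bimodality_calibration <- function(n_runs = 100, n_outer = 500,
                                   n_reps = 10000, seed = 1) {
  with_seed(seed, {
    detect <- mean(vapply(seq_len(n_runs), function(r) {
      ref <- stats::runif(28, 0, 0.5)
      obs <- c(stats::rnorm(6, 0.02, 0.01), stats::rnorm(4, 0.45, 0.01))
      bootstrap_bimodality(ref, obs, n_draws = 10, n_reps = n_reps)$
        p_one_sided < 0.05
    }, TRUE))
    self <- mean(vapply(seq_len(n_outer), function(r) {
      ref <- stats::runif(28, 0, 0.5)
      obs <- sample(ref, 10, replace = TRUE)
      bootstrap_bimodality(ref, obs, n_draws = 10, n_reps = n_reps)$
        p_one_sided < 0.05
    }, TRUE))
    list(detect_rate = detect, self_rejection_rate = self)
  })
}
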