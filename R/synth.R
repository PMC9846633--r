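#' Bi-exponential phasic IPSC waveform
#'
#' Canonical fast IPSC shape: a first-order rise multiplying a bi-exponential
#' decay, returned in raw amplifier sign (negative-going inward current):
#' `w(t) = -(1 - exp(-t/rise_tau)) * (A1*exp(-t/TAU1) + A2*exp(-t/TAU2))`
#' for `t >= 0`, zero before. With `rise_tau -> 0` the analytic charge
#' magnitude is `A1*TAU1 + A2*TAU2` (pA·ms).
#'
#' @param t time grid in ms from event onset (values < 0 give 0).
#' @param params list with `A1`, `TAU1`, `A2`, `TAU2` (pA, ms) and `rise_tau`
#'   (ms, 0 allowed for an instantaneous rise).
#' @return current trace in pA (raw sign).
#' @export
phasic_waveform <- function(t, params) {
  with(params, {
    if (TAU1 <= 0 || TAU2 <= 0) stopf("time constants must be positive")
    if (rise_tau < 0) stopf("rise_tau must be >= 0")
    rise <- if (rise_tau == 0) 1 else (1 - exp(-pmax(t, 0) / rise_tau))
    w <- -rise * (A1 * exp(-pmax(t, 0) / TAU1) + A2 * exp(-pmax(t, 0) / TAU2))
    w[t < 0] <- 0
    w
  })
}

# analytic charge magnitude (pA*ms) of phasic_waveform over [0, Inf)
phasic_charge_analytic <- function(params) {
  with(params, {
    r <- rise_tau
    A1 * TAU1^2 / (r + TAU1) + A2 * TAU2^2 / (r + TAU2)
  })
}

# mono-exponential event with first-order rise, raw sign
mono_waveform <- function(t, A, TAU, rise_tau) {
  phasic_waveform(t, list(A1 = A, TAU1 = TAU, A2 = 0, TAU2 = TAU,
                          rise_tau = rise_tau))
}

# slow spillover tail carrying total charge q_slow (pC) with decay tau_slow
spillover_waveform <- function(t, q_slow, tau_slow, rise_tau) {
  A <- 1000 * q_slow * (rise_tau + tau_slow) / tau_slow^2
  mono_waveform(t, A, tau_slow, rise_tau)
}

# time from onset to waveform peak (ms), on a fine grid
waveform_peak_lag <- function(params, horizon_ms = 30, dt = 0.005) {
  tg <- seq(0, horizon_ms, by = dt)
  tg[which.min(phasic_waveform(tg, params))]
}

# white Gaussian noise low-passed at cutoff_khz and rescaled to sd (pA);
# generated as one stream and reshaped to a n_samples x n_traces matrix
gen_noise <- function(n_samples, n_traces, sd, sampling_rate,
                      cutoff_khz = 3) {
  if (sd <= 0) return(matrix(0, n_samples, n_traces))
  x <- stats::rnorm(n_samples * n_traces)
  if (!is.null(cutoff_khz) && is.finite(cutoff_khz) &&
      cutoff_khz * 1000 < sampling_rate / 2) {
    bf <- signal::butter(4, 2 * cutoff_khz * 1000 / sampling_rate, "low")
    x <- signal::filtfilt(bf, x)
    x <- x / stats::sd(x)
  }
  matrix(x * sd, n_samples, n_traces)
}

#' Configuration for a synthetic optogenetic pair
#'
#' Defaults emulate the study conditions of adult Golgi-to-granule-cell
#' transmission: spike success 0.62 per flash, postsynaptic failure rate
#' 0.16, delayed-event prevalence 0.25 among successes, fast bi-exponential
#' kinetics (TAU1 2 ms, TAU2 16.5 ms), delayed mono-exponential kinetics
#' (TAU 10 ms), a slow spillover tail (0.6 pC, tau 359 ms) whose amplitude on
#' postsynaptic failures is one third of that on successes, mean peak-to-peak
#' synaptic delay 1.5 ms, and 3 kHz low-passed Gaussian recording noise.
#'
#' @param connected is the pair synaptically connected.
#' @param n_trials number of flashes.
#' @param p_ap probability that a flash evokes a presynaptic AP.
#' @param p_fail postsynaptic failure probability given an AP.
#' @param p_delayed probability that a success is a delayed (slow-onset) event.
#' @param phasic_params list `A1`, `TAU1`, `A2`, `TAU2`, `rise_tau` (pA/ms).
#' @param delayed_params list `A`, `TAU`, `onset_shift`, `rise_tau`.
#' @param spillover_params list `q_slow` (pC), `tau_slow` (ms), `rise_tau`,
#'   `fail_fraction` (spillover scale on postsynaptic failures),
#'   `unconnected_fraction` (scale on AP trials of unconnected pairs).
#' @param delay_mean,delay_sd mean and SD (ms) of the peak-to-peak synaptic
#'   delay (AP peak to IPSC peak); the generator converts this to an onset
#'   time using the deterministic waveform peak lag.
#' @param gap_junction if `TRUE`, adds ~1 ms of extra latency, emulating
#'   spike propagation through an electrically coupled neighbouring cell.
#' @param ap_latency,ap_jitter spike latency after the flash (ms).
#' @param noise_sd recording noise SD in pA (after low-pass).
#' @param noise_cutoff_khz low-pass cutoff for the noise model (kHz).
#' @param amplitude_cv trial-to-trial multiplicative (lognormal) CV of event
#'   amplitude.
#' @param sweep_ms,pre_ms sweep duration and pre-stimulus baseline (ms).
#' @param sampling_rate Hz.
#' @param phenotype,pair_id metadata passed through to the recording.
#' @param seed integer seed (local to the simulation).
#' @return a `synth_pair_config` list.
#' @export
synth_pair_config <- function(connected = TRUE, n_trials = 60, p_ap = 0.62,
                              p_fail = 0.16, p_delayed = 0.25,
                              phasic_params = list(A1 = 40, TAU1 = 2, A2 = 15,
                                                   TAU2 = 16.5, rise_tau = 0.3),
                              delayed_params = list(A = 12, TAU = 10,
                                                    onset_shift = 0.5,
                                                    rise_tau = 2.5),
                              spillover_params = list(q_slow = 0.6,
                                                      tau_slow = 359,
                                                      rise_tau = 5,
                                                      fail_fraction = 1 / 3,
                                                      unconnected_fraction = 0.18),
                              delay_mean = 1.5, delay_sd = 0.25,
                              gap_junction = FALSE,
                              ap_latency = 3, ap_jitter = 0.2,
                              noise_sd = 5, noise_cutoff_khz = 3,
                              amplitude_cv = 0.3,
                              sweep_ms = 500, pre_ms = 50,
                              sampling_rate = 20000,
                              phenotype = "unknown", pair_id = "synth",
                              seed = NULL) {
  cfg <- as.list(environment())
  for (p in c("p_ap", "p_fail", "p_delayed"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must be in [0, 1]", p)
  if (n_trials < 1) stopf("n_trials must be >= 1")
  if (with(phasic_params, TAU2 <= TAU1 || TAU1 <= 0))
    stopf("need TAU2 > TAU1 > 0")
  if (spillover_params$tau_slow <= phasic_params$TAU2)
    stopf("tau_slow must exceed TAU2")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  structure(cfg, class = "synth_pair_config")
}

#' Simulate one optogenetic pair recording with ground truth
#'
#' Each flash draws a presynaptic AP (Bernoulli `p_ap`); on connected pairs,
#' successes place a phasic or delayed event at the spike time plus the
#' synaptic delay, with lognormal amplitude variability, and add a slow
#' spillover tail. Postsynaptic failures keep a reduced spillover tail
#' (`fail_fraction`, reflecting release at sites of the same glomerulus not
#' contacting the recorded cell); unconnected pairs contribute only a small
#' spillover on AP trials. Reproducible given `config$seed`.
#'
#' @param config a [synth_pair_config()].
#' @return list with `pair` (a [pair_recording] whose sweep labels hold the
#'   true classes) and `truth` (per-trial data.frame plus the generating
#'   parameters).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "synth_pair_config"))
  with_seed(config$seed, simulate_pair_impl(config))
}

simulate_pair_impl <- function(cfg) {
  fs <- cfg$sampling_rate
  n_samp <- as.integer(round(cfg$sweep_ms * fs / 1000))
  n <- cfg$n_trials
  dt <- 1000 / fs
  tgrid <- (seq_len(n_samp) - 1) * dt

  ap <- stats::runif(n) < cfg$p_ap
  ap_time <- ifelse(ap, cfg$pre_ms +
                      stats::rnorm(n, cfg$ap_latency, cfg$ap_jitter), NA_real_)
  ipsc <- rep(NA, n)
  cls <- rep("undetermined", n)
  if (cfg$connected) {
    ipsc[ap] <- stats::runif(sum(ap)) >= cfg$p_fail
    cls[ap & !ipsc %in% TRUE] <- "failure"
    succ <- which(ap & ipsc %in% TRUE)
    delayed <- stats::runif(length(succ)) < cfg$p_delayed
    cls[succ] <- ifelse(delayed, "delayed", "phasic")
  } else {
    ipsc[ap] <- FALSE
    cls[ap] <- "failure"
  }

  cv <- cfg$amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  mult <- if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)
  delay <- stats::rnorm(n, cfg$delay_mean, cfg$delay_sd) +
    if (cfg$gap_junction) 1 else 0
  delay <- pmax(delay, 0.2)
  peak_lag <- waveform_peak_lag(cfg$phasic_params)

  sp <- cfg$spillover_params
  q_scale <- numeric(n)
  q_scale[ap] <- if (cfg$connected)
    ifelse(ipsc[ap] %in% TRUE, 1, sp$fail_fraction) else sp$unconnected_fraction

  traces <- gen_noise(n_samp, n, cfg$noise_sd, fs, cfg$noise_cutoff_khz)
  onset <- rep(NA_real_, n)
  for (i in which(ap)) {
    on_i <- ap_time[i] + delay[i] - peak_lag
    if (cls[i] == "delayed") on_i <- on_i + cfg$delayed_params$onset_shift
    onset[i] <- on_i
    trel <- tgrid - on_i
    ev <- numeric(n_samp)
    if (cls[i] == "phasic") {
      ev <- phasic_waveform(trel, cfg$phasic_params) * mult[i]
    } else if (cls[i] == "delayed") {
      ev <- mono_waveform(trel, cfg$delayed_params$A, cfg$delayed_params$TAU,
                          cfg$delayed_params$rise_tau) * mult[i]
    }
    if (q_scale[i] > 0)
      ev <- ev + spillover_waveform(trel, sp$q_slow * q_scale[i] * mult[i],
                                    sp$tau_slow, sp$rise_tau)
    traces[, i] <- traces[, i] + ev
  }

  sweeps <- lapply(seq_len(n), function(i) {
    sweep_record(traces[, i], fs, cfg$pre_ms, ap_time = ap_time[i],
                 labels = list(ap_success = ap[i], ipsc_success = ipsc[i],
                               event_class = cls[i]))
  })
  pair <- pair_recording(cfg$pair_id, sweeps, phenotype = cfg$phenotype,
                         protocol = "optogenetic_0p37Hz",
                         connected = cfg$connected)
  truth <- list(trials = data.frame(trial = seq_len(n), ap = ap,
                                    ap_time = ap_time, ipsc = ipsc,
                                    event_class = cls, amp_mult = mult,
                                    onset_ms = onset, delay_ms = delay,
                                    q_slow_scale = q_scale,
                                    stringsAsFactors = FALSE),
                p_fail = cfg$p_fail, phasic_params = cfg$phasic_params,
                delayed_params = cfg$delayed_params,
                spillover_params = sp, delay_mean = cfg$delay_mean,
                peak_lag = peak_lag)
  list(pair = pair, truth = truth)
}

#' Simulate loose-patch cell-attached sweeps for AP-detection calibration
#'
#' The extracellular spike is modelled as a derivative-of-Gaussian biphasic
#' waveform centred on the spike time.
#'
#' @param n_trials number of sweeps.
#' @param p_ap spike probability per flash.
#' @param spike_latency spike time after the stimulus (ms).
#' @param amp spike peak amplitude (pA); SNR = `amp / noise_sd`.
#' @param width_ms Gaussian width of the biphasic waveform.
#' @param noise_sd,noise_cutoff_khz recording-noise model.
#' @param stim_time,sweep_ms,sampling_rate sweep geometry.
#' @param seed integer seed (local).
#' @return list with `sweeps` (list of [sweep_record]; `ap_time` holds the
#'   true spike time) and `truth` data.frame.
#' @export
simulate_loose_patch <- function(n_trials = 100, p_ap = 0.62,
                                 spike_latency = 3, amp = 50, width_ms = 0.15,
                                 noise_sd = 5, noise_cutoff_khz = 3,
                                 stim_time = 20, sweep_ms = 40,
                                 sampling_rate = 20000, seed = NULL) {
  with_seed(seed, {
    fs <- sampling_rate
    n_samp <- as.integer(round(sweep_ms * fs / 1000))
    tgrid <- (seq_len(n_samp) - 1) * 1000 / fs
    spikes <- stats::runif(n_trials) < p_ap
    traces <- gen_noise(n_samp, n_trials, noise_sd, fs, noise_cutoff_khz)
    t_spk <- rep(NA_real_, n_trials)
    for (i in which(spikes)) {
      t_spk[i] <- stim_time + spike_latency
      u <- (tgrid - t_spk[i]) / width_ms
      traces[, i] <- traces[, i] - (amp / exp(-0.5)) * u * exp(-u^2 / 2)
    }
    sweeps <- lapply(seq_len(n_trials), function(i)
      sweep_record(traces[, i], fs, stim_time, ap_time = t_spk[i]))
    list(sweeps = sweeps,
         truth = data.frame(trial = seq_len(n_trials), ap = spikes,
                            spike_time = t_spk))
  })
}

#' Configuration for a synthetic 10 Hz pharmacology time course
#'
#' Defaults emulate the glycine bath-application experiments: 3 min baseline,
#' 5 min drug application, washout to 15 min, multiplicative rundown losing
#' 20% of the response per 10 min, and a glycine effect that scales the
#' evoked amplitude to 0.8 and the slow decay (A2) fraction to 0.8 with
#' first-order onset kinetics (tau 2 min), frozen at its reached level after
#' the application ends (no recovery on washout). With these values the
#' charge ratio between the end-of-application and baseline epochs
#' reproduces the 0.62 observed under glycine (0.83 in control from rundown
#' alone).
#'
#' @param duration_min total recording duration (min).
#' @param stim_rate stimulation rate in Hz (default 10).
#' @param baseline_min baseline duration before any drug (min).
#' @param drug `"glycine"` or `"none"` (control).
#' @param drug_onset_min,drug_duration_min drug epoch (min).
#' @param rundown_rate fractional response loss per 10 min of stimulation.
#' @param glycine_effect list `amplitude_scale`, `a2_fraction_scale`
#'   (asymptotic multiplicative scales in (0, 1]) and `onset_tau_min`.
#' @param eipsc_params evoked-IPSC waveform: `amp` (peak-scale pA),
#'   `a2_fraction`, `TAU1`, `TAU2`, `rise_tau`.
#' @param amplitude_cv per-stimulus lognormal amplitude CV.
#' @param noise_sd,noise_cutoff_khz recording-noise model (pA, kHz).
#' @param sampling_rate Hz.
#' @param seed integer seed (local).
#' @return a `synth_timecourse_config` list.
#' @export
synth_timecourse_config <- function(duration_min = 15, stim_rate = 10,
                                    baseline_min = 3, drug = c("glycine", "none"),
                                    drug_onset_min = 3, drug_duration_min = 5,
                                    rundown_rate = 0.2,
                                    glycine_effect = list(amplitude_scale = 0.8,
                                                          a2_fraction_scale = 0.8,
                                                          onset_tau_min = 2),
                                    eipsc_params = list(amp = 60,
                                                        a2_fraction = 0.5,
                                                        TAU1 = 3.5, TAU2 = 36.5,
                                                        rise_tau = 0.5),
                                    amplitude_cv = 0.1,
                                    noise_sd = 3, noise_cutoff_khz = 3,
                                    sampling_rate = 20000, seed = NULL) {
  drug <- match.arg(drug)
  cfg <- as.list(environment())
  if (drug_onset_min < baseline_min)
    stopf("drug_onset_min must be >= baseline_min")
  sc <- unlist(glycine_effect[c("amplitude_scale", "a2_fraction_scale")])
  if (any(sc <= 0 | sc > 1)) stopf("glycine scales must lie in (0, 1]")
  if (rundown_rate < 0 || rundown_rate >= 1)
    stopf("rundown_rate must be in [0, 1)")
  structure(cfg, class = "synth_timecourse_config")
}

#' Simulate a continuous 10 Hz evoked-IPSC recording
#'
#' Generates a continuous voltage-clamp trace with one evoked IPSC per
#' stimulus. The per-stimulus amplitude follows multiplicative exponential
#' rundown calibrated so the fractional loss after 10 min equals
#' `rundown_rate`; after drug onset the amplitude and the A2 fraction are
#' scaled with first-order onset kinetics as described in
#' [synth_timecourse_config()].
#'
#' @param config a [synth_timecourse_config()].
#' @return list with `samples` (continuous trace, pA), `sampling_rate`,
#'   `stim_times` (ms) and `truth` (per-stimulus data.frame: time, amplitude
#'   factor, a2 fraction, expected charge in pC).
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "synth_timecourse_config"))
  with_seed(config$seed, simulate_timecourse_impl(config))
}

simulate_timecourse_impl <- function(cfg) {
  fs <- cfg$sampling_rate
  total_ms <- cfg$duration_min * 60 * 1000
  isi <- 1000 / cfg$stim_rate
  stim_times <- seq(100, total_ms - isi, by = isi)
  m <- stim_times / 60000                     # minutes
  n_samp <- as.integer(round(total_ms * fs / 1000))

  rund <- (1 - cfg$rundown_rate)^(m / 10)
  g_amp <- rep(1, length(m))
  g_a2 <- rep(1, length(m))
  if (cfg$drug == "glycine") {
    gl <- cfg$glycine_effect
    el <- pmin(pmax(m - cfg$drug_onset_min, 0), cfg$drug_duration_min)
    onset <- 1 - exp(-el / gl$onset_tau_min)
    g_amp <- 1 - (1 - gl$amplitude_scale) * onset
    g_a2 <- 1 - (1 - gl$a2_fraction_scale) * onset
  }
  ep <- cfg$eipsc_params
  cv <- cfg$amplitude_cv
  sdlog <- sqrt(log(1 + cv^2))
  mult <- if (cv > 0) stats::rlnorm(length(m), -sdlog^2 / 2, sdlog)
          else rep(1, length(m))
  amp <- ep$amp * rund * g_amp * mult
  a2f <- ep$a2_fraction * g_a2

  trace <- as.numeric(gen_noise(n_samp, 1L, cfg$noise_sd, fs,
                                cfg$noise_cutoff_khz))
  # waveform support: 4 inter-stimulus intervals of tail
  dt <- 1000 / fs
  n_ev <- as.integer(round(4 * isi / dt))
  tev <- (seq_len(n_ev) - 1) * dt
  rise <- if (ep$rise_tau == 0) 1 else 1 - exp(-tev / ep$rise_tau)
  e1 <- rise * exp(-tev / ep$TAU1)
  e2 <- rise * exp(-tev / ep$TAU2)
  for (k in seq_along(stim_times)) {
    i0 <- ms_to_index(stim_times[k], fs)
    i1 <- min(n_samp, i0 + n_ev - 1L)
    idx <- i0:i1
    a2 <- amp[k] * a2f[k]
    a1 <- amp[k] * (1 - a2f[k])
    trace[idx] <- trace[idx] - (a1 * e1[seq_along(idx)] +
                                a2 * e2[seq_along(idx)])
  }
  q_exp <- (amp * ((1 - a2f) * ep$TAU1^2 / (ep$rise_tau + ep$TAU1) +
                   a2f * ep$TAU2^2 / (ep$rise_tau + ep$TAU2))) / 1000
  list(samples = trace, sampling_rate = fs, stim_times = stim_times,
       truth = data.frame(stim = seq_along(stim_times), time_min = m,
                          amp_factor = rund * g_amp, amp_pA = amp,
                          a2_fraction = a2f, q_expected_pC = q_exp))
}
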