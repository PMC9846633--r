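# Shared oracles and tiny fixture factories. Oracles are deliberately naive
# (enumeration / direct quadrature / loop-based statistics) and independent
# of the implementation paths they check.

# brute-force optimum over ALL 2-partitions (not just sorted splits)
brute_force_inertia <- function(v) {
  n <- length(v)
  best <- Inf
  for (m in seq_len(2^n - 2)) {
    a <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    w <- sum((v[a] - mean(v[a]))^2) + sum((v[!a] - mean(v[!a]))^2)
    best <- min(best, w)
  }
  best
}

# naive loop implementation of the sliding-difference statistic at one time
naive_slide_stat <- function(samples, fs, t_ms) {
  idx <- function(ms) round(ms * fs / 1000) + 1
  long <- samples[idx(t_ms - 10.3):(idx(t_ms - 0.3) - 1)]
  short <- samples[idx(t_ms):(idx(t_ms + 0.5) - 1)]
  mean(long) - mean(short)
}

# quadrature charge (pC) of a waveform function over [a, b] ms
quad_charge <- function(f, a, b, dt = 0.001) {
  tg <- seq(a, b, by = dt)
  w <- f(tg)
  -(sum(w) - (w[1] + w[length(w)]) / 2) * dt / 1000
}

# noiseless deterministic pair: every trial identical phasic event
noiseless_config <- function(...) {
  synth_pair_config(p_ap = 1, p_fail = 0, p_delayed = 0, noise_sd = 0,
                    amplitude_cv = 0, delay_sd = 0, ap_jitter = 0, ...)
}

# a flat sweep with optional added current segments
flat_sweep <- function(dur_ms = 100, fs = 20000, stim = 50, value = 0) {
  sweep_record(rep(value, round(dur_ms * fs / 1000)), fs, stim)
}
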