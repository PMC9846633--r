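test_that("phasic waveform has the closed-form charge", {
  p <- list(A1 = 40, TAU1 = 2, A2 = 15, TAU2 = 16, rise_tau = 0)
  # instantaneous rise: |Q| = A1*TAU1 + A2*TAU2 = 320 pA*ms = 0.32 pC
  tg <- seq(0, 500, by = 0.05)
  q_num <- -sum(phasic_waveform(tg, p)) * 0.05 / 1000
  expect_equal(q_num, 0.32, tolerance = 0.005)
  # quadrature at the native 20 kHz grid agrees with the closed form < 0.5%
  p2 <- list(A1 = 40, TAU1 = 2, A2 = 15, TAU2 = 16, rise_tau = 0.3)
  q_closed <- phasic_charge_analytic(p2) / 1000
  q_grid <- quad_charge(function(t) phasic_waveform(t, p2), 0, 500, 0.05)
  expect_equal(q_grid, q_closed, tolerance = 0.005)
  # degenerate cases
  expect_true(all(phasic_waveform(tg, list(A1 = 0, TAU1 = 2, A2 = 0,
                                           TAU2 = 16, rise_tau = 0)) == 0))
  expect_error(phasic_waveform(tg, list(A1 = 1, TAU1 = -2, A2 = 0, TAU2 = 16,
                                        rise_tau = 0)), "positive")
})

test_that("simulate_pair is deterministic under seed and validates config", {
  cfg <- synth_pair_config(n_trials = 6, sweep_ms = 80, pre_ms = 30, seed = 5)
  s1 <- simulate_pair(cfg)
  s2 <- simulate_pair(cfg)
  expect_identical(s1$pair$sweeps[[3]]$samples, s2$pair$sweeps[[3]]$samples)
  expect_identical(s1$truth$trials, s2$truth$trials)
  s3 <- simulate_pair(synth_pair_config(n_trials = 6, sweep_ms = 80,
                                        pre_ms = 30, seed = 6))
  expect_false(identical(s1$pair$sweeps[[3]]$samples,
                         s3$pair$sweeps[[3]]$samples))
  expect_error(synth_pair_config(n_trials = 0), "n_trials")
  expect_error(synth_pair_config(p_fail = 1.2), "p_fail")
  expect_error(synth_pair_config(
    phasic_params = list(A1 = 1, TAU1 = 5, A2 = 1, TAU2 = 2, rise_tau = 0)),
    "TAU2 > TAU1")
})

test_that("noiseless trials carry the analytic 5-ms window charge", {
  sim <- simulate_pair(noiseless_config(n_trials = 5, sweep_ms = 200,
                                        seed = 3))
  tr <- sim$truth$trials
  pp <- sim$truth$phasic_params
  sp <- sim$truth$spillover_params
  for (i in 1:5) {
    ap <- tr$ap_time[i]
    onset <- tr$onset_ms[i]
    event <- function(t) phasic_waveform(t - onset, pp) +
      spillover_waveform(t - onset, sp$q_slow, sp$tau_slow, sp$rise_tau)
    # oracle: quadrature of the waveform, minus the 10-ms local baseline
    base <- -quad_charge(event, ap - 9, ap + 1) / 10 * 1000    # mean pA
    q_true <- quad_charge(function(t) event(t) - base, ap + 1, ap + 6)
    expect_equal(trial_charge(sim$pair$sweeps[[i]]), q_true,
                 tolerance = 0.02)
  }
})

test_that("ground-truth failure counts follow the binomial law", {
  sim <- simulate_pair(synth_pair_config(n_trials = 1000, p_ap = 1,
                                         p_fail = 0.2, sweep_ms = 30,
                                         pre_ms = 20, noise_sd = 0,
                                         sampling_rate = 2000, seed = 8))
  n_fail <- sum(sim$truth$trials$ipsc %in% FALSE)
  ci <- qbinom(c(0.025, 0.975), 1000, 0.2)
  expect_gte(n_fail, ci[1])
  expect_lte(n_fail, ci[2])
})

test_that("spillover scales on failures equal the configured fraction", {
  sim <- simulate_pair(synth_pair_config(n_trials = 400, p_ap = 1,
                                         p_fail = 0.4, sweep_ms = 30,
                                         pre_ms = 20, noise_sd = 0,
                                         sampling_rate = 2000, seed = 12))
  tr <- sim$truth$trials
  r <- mean(tr$q_slow_scale[tr$ipsc %in% FALSE]) /
    mean(tr$q_slow_scale[tr$ipsc %in% TRUE])
  expect_equal(r, 1 / 3, tolerance = 1e-9)
})

test_that("timecourse rundown is calibrated to the 10-min fractional loss", {
  cfg <- synth_timecourse_config(duration_min = 10.5, rundown_rate = 0.2,
                                 drug = "none", amplitude_cv = 0,
                                 noise_sd = 0, sampling_rate = 4000,
                                 seed = 30)
  tc <- simulate_timecourse(cfg)
  sweeps <- segment_train(tc$samples, tc$sampling_rate, tc$stim_times,
                          c(-10, 90))
  ser <- suppressWarnings(qeipsc_series(sweeps))
  q0 <- ser$q_pC[1]
  q10 <- ser$q_pC[which.min(abs(ser$time_min - 10))]
  expect_equal(q10 / q0, 0.8, tolerance = 0.02)
})

test_that("flat timecourse stays flat without rundown or drug", {
  cfg <- synth_timecourse_config(duration_min = 4, rundown_rate = 0,
                                 drug = "none", amplitude_cv = 0,
                                 noise_sd = 0, sampling_rate = 4000,
                                 seed = 31)
  tc <- simulate_timecourse(cfg)
  sweeps <- segment_train(tc$samples, tc$sampling_rate, tc$stim_times,
                          c(-10, 90))
  ser <- suppressWarnings(qeipsc_series(sweeps))
  expect_true(all(abs(ser$normalized_q - 1) < 0.01))
})
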