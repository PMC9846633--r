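make_pulse_sweep <- function(level = -10, from = 51, to = 56.5, dc = 0,
                             fs = 20000) {
  x <- rep(dc, 2000)
  i0 <- round(from * fs / 1000) + 1
  i1 <- round(to * fs / 1000) + 1
  x[i0:i1] <- x[i0:i1] + level
  sweep_record(x, fs, 30)
}

test_that("trial charge matches analytic values and ignores DC offsets", {
  expect_identical(trial_charge(flat_sweep(), ap_time = 50), 0)
  # -10 pA pulse spanning the whole 5-ms window: +0.05 pC
  sw <- make_pulse_sweep(level = -10, from = 50.5, to = 56.5)
  expect_equal(trial_charge(sw, ap_time = 49.5), 0.05, tolerance = 1e-9)
  # unchanged on a -5 pA DC offset
  sw_dc <- make_pulse_sweep(level = -10, from = 50.5, to = 56.5, dc = -5)
  expect_equal(trial_charge(sw_dc, ap_time = 49.5),
               trial_charge(sw, ap_time = 49.5), tolerance = 1e-12)
  expect_error(trial_charge(flat_sweep(), ap_time = 97), "out of range")
  expect_error(trial_charge(flat_sweep(), ap_time = 5), "out of range")
})

test_that("trial charge is linear in the trace", {
  set.seed(41)
  x <- rnorm(2000, sd = 4)
  y <- rnorm(2000, sd = 4)
  fs <- 20000
  q <- function(v) trial_charge(sweep_record(v, fs, 30), ap_time = 40)
  expect_equal(q(2 * x + 3 * y), 2 * q(x) + 3 * q(y), tolerance = 1e-10)
})

test_that("baseline charge null is centred on zero and symmetric", {
  expect_identical(unique(baseline_charge_distribution(
    list(flat_sweep(dur_ms = 60, stim = 40)), 200, seed = 1)), 0)
  set.seed(42)
  sweeps <- lapply(1:20, function(i)
    sweep_record(rnorm(1200, sd = 5), 20000, 50))
  d <- baseline_charge_distribution(sweeps, 10000, seed = 2)
  sem <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * sem)
  skw <- mean((d - mean(d))^3) / sd(d)^3
  expect_lt(abs(skw), 0.2)
  expect_error(baseline_charge_distribution(
    list(flat_sweep(stim = 12)), 10), "16 ms")
})

test_that("peak and synaptic delay recover the generator ground truth", {
  sim <- simulate_pair(noiseless_config(n_trials = 4, sweep_ms = 200,
                                        seed = 14))
  tr <- sim$truth$trials
  for (i in 1:4) {
    pk <- peak_and_delay(sim$pair$sweeps[[i]])
    expect_equal(pk$delay, tr$delay_ms[i], tolerance = 0.06)  # one sample
    expect_false(pk$undetermined)
  }
  # pure noise: delay reported but flagged undetermined
  set.seed(15)
  noise <- sweep_record(rnorm(2000, sd = 5), 20000, 50)
  pk <- peak_and_delay(noise, ap_time = 53)
  expect_true(is.finite(pk$delay))
  expect_true(pk$undetermined)
})

test_that("gap-junction routing adds ~1 ms to the synaptic delay", {
  delays <- lapply(c(FALSE, TRUE), function(gj) {
    sim <- simulate_pair(synth_pair_config(
      n_trials = 30, p_ap = 1, p_fail = 0, p_delayed = 0, noise_sd = 2,
      gap_junction = gj, sweep_ms = 200, seed = 16))
    avg <- average_sweeps(sim$pair$sweeps,
                          ap_time = mean(sim$truth$trials$ap_time))
    peak_and_delay(avg)$delay
  })
  expect_equal(delays[[2]] - delays[[1]], 1, tolerance = 0.15)
})

test_that("slow charge integration matches the mono-exponential closed form", {
  # tail A = 2 pA, tau = 359 ms starting at the "peak"; integrate from
  # peak+36 to 2 s: A*tau*(exp(-36/359) - exp(-2000/359))
  fs <- 2000
  dur <- 2500
  t <- (seq_len(dur * fs / 1000) - 1) * 1000 / fs
  pk_t <- 100
  x <- ifelse(t >= pk_t, -2 * exp(-(t - pk_t) / 359), 0)
  sw <- sweep_record(x, fs, 50)
  q <- slow_charge(sw, ap_time = 98, horizon = c(98, 2098), peak_time = pk_t)
  q_true <- 2 * 359 * (exp(-36 / 359) - exp(-2000 / 359)) / 1000
  expect_equal(q, q_true, tolerance = 0.01 * q_true)
  expect_identical(slow_charge(flat_sweep(dur_ms = 300, fs = 2000),
                               ap_time = 60, horizon = c(60, 290),
                               peak_time = 62), 0)
  expect_error(slow_charge(sw, ap_time = 98, horizon = c(98, 3000)),
               "beyond")
})

test_that("trial metrics table flags AP failures with NA metrics", {
  sim <- simulate_pair(synth_pair_config(n_trials = 20, p_ap = 0.5,
                                         sweep_ms = 100, seed = 17))
  tm <- trial_metrics(sim$pair)
  expect_identical(tm$ap_success, sim$truth$trials$ap)
  expect_true(all(is.na(tm$q_fast_pC[!tm$ap_success])))
  expect_true(all(is.finite(tm$q_fast_pC[tm$ap_success])))
})
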