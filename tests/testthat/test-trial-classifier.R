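test_that("failure rate follows the twice-negative-charge definition", {
  r <- failure_rate(c(-0.1, 0.1, 2, 3, 4))
  expect_equal(r$p_fail, 0.4)
  expect_identical(sort(r$failure_trials), c(1L, 2L))
  expect_equal(r$threshold_charge, 0.1)
  # all positive and large: no failures
  expect_equal(failure_rate(c(1, 2, 3))$p_fail, 0)
  expect_error(failure_rate(numeric(0)), "empty")
  # capped at 1 when more than half the charges are negative
  expect_warning(rc <- failure_rate(c(-3, -2, -1, 1)), "capping")
  expect_equal(rc$p_fail, 1)
})

test_that("failure rate is equivariant under sign-preserving shifts", {
  set.seed(51)
  q <- c(rnorm(40, 2, 0.3), rnorm(10, 0, 0.4))
  shift <- min(abs(q)) * 0.5
  expect_equal(failure_rate(q)$p_fail, failure_rate(q + shift)$p_fail)
  expect_equal(failure_rate(q)$p_fail, failure_rate(q - shift)$p_fail)
})

test_that("perfectly separated successes recover the exact failure set", {
  # failures symmetric about 0 with an even split; successes far away
  fails <- c(-0.3, -0.2, -0.1, 0.1, 0.2, 0.3)
  succ <- seq(5, 8, length.out = 14)
  q <- c(fails, succ)
  r <- failure_rate(q)
  expect_identical(sort(r$failure_trials), 1:6)
  expect_equal(r$p_fail, 6 / 20)
})

test_that("connectivity classification needs a right shift and small p", {
  x <- rnorm(30)
  r <- classify_connectivity(x, x)
  expect_equal(r$ks_statistic, 0)
  expect_false(r$connected)
  expect_error(classify_connectivity(rnorm(5), rnorm(50)), ">= 10")
  # clearly connected pair
  set.seed(52)
  r2 <- classify_connectivity(rnorm(50, 3), rnorm(1000))
  expect_true(r2$connected)
  expect_lt(r2$ks_p, 1e-4)
  # left shift is never called connected, however significant
  r3 <- classify_connectivity(rnorm(50, -3), rnorm(1000))
  expect_false(r3$connected)
})

test_that("slide statistic matches a naive loop implementation", {
  set.seed(53)
  sim <- simulate_pair(synth_pair_config(n_trials = 1, p_ap = 1, p_fail = 0,
                                         p_delayed = 0, noise_sd = 3,
                                         seed = 53))
  sw <- sim$pair$sweeps[[1]]
  d <- ipsckit:::slide_statistic(sw$samples, sw$sampling_rate)
  for (t_ms in c(20, 45, 52.3, 54, 70)) {
    i <- round(t_ms * sw$sampling_rate / 1000) + 1
    expect_equal(d[i], naive_slide_stat(sw$samples, sw$sampling_rate, t_ms),
                 tolerance = 1e-10)
  }
})

test_that("fast rise time lands on the fast-component rise", {
  sim <- simulate_pair(noiseless_config(n_trials = 6, sweep_ms = 200,
                                        seed = 54))
  avg <- average_sweeps(sim$pair$sweeps,
                        ap_time = mean(sim$truth$trials$ap_time))
  frt <- fast_rise_time(avg)
  # oracle: argmax of the naive statistic on a fine grid
  grid <- seq(avg$ap_time, avg$ap_time + 6, by = 0.05)
  dg <- vapply(grid, function(tt)
    naive_slide_stat(avg$samples, avg$sampling_rate, tt), 0)
  expect_equal(frt$time, grid[which.max(abs(dg))], tolerance = 0.15)
  expect_false(frt$undetermined)
  # flat trace: statistic identically zero, flagged undetermined
  frt0 <- fast_rise_time(flat_sweep(), ap_time = 53)
  expect_true(frt0$undetermined)
  expect_equal(frt0$stat_max, 0)
})

test_that("noiseless phasic and delayed trials classify correctly", {
  simp <- simulate_pair(noiseless_config(n_trials = 4, sweep_ms = 200,
                                         seed = 55))
  avgp <- average_sweeps(simp$pair$sweeps,
                         ap_time = mean(simp$truth$trials$ap_time))
  frt <- fast_rise_time(avgp)
  simd <- simulate_pair(synth_pair_config(
    n_trials = 4, p_ap = 1, p_fail = 0, p_delayed = 1, noise_sd = 0,
    amplitude_cv = 0, delay_sd = 0, ap_jitter = 0, sweep_ms = 200,
    seed = 55))
  # tiny noise floor for the per-trial baseline SD; signal >> threshold
  bl <- list(mean = 0, sd = 1e-3)
  expect_identical(
    classify_phasic_delayed(simp$pair$sweeps, frt, bl)$event_class,
    rep("phasic", 4))
  # delayed trials have no fast component at the phasic rise time
  cls_d <- classify_phasic_delayed(simd$pair$sweeps, frt,
                                   list(mean = 0, sd = 2))
  expect_identical(cls_d$event_class, rep("delayed", 4))
  expect_error(classify_phasic_delayed(simp$pair$sweeps, NA_real_),
               "undefined")
})

test_that("delayed-only pairs yield far smaller slide maxima than phasic", {
  simp <- simulate_pair(synth_pair_config(n_trials = 30, p_ap = 1,
                                          p_fail = 0, p_delayed = 0,
                                          noise_sd = 5, sweep_ms = 160,
                                          seed = 56))
  simd <- simulate_pair(synth_pair_config(n_trials = 30, p_ap = 1,
                                          p_fail = 0, p_delayed = 1,
                                          noise_sd = 5, sweep_ms = 160,
                                          seed = 56))
  stat_of <- function(sim) {
    avg <- average_sweeps(sim$pair$sweeps,
                          ap_time = mean(sim$truth$trials$ap_time))
    abs(fast_rise_time(avg)$stat_max)
  }
  expect_lt(stat_of(simd), 0.4 * stat_of(simp))
})
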