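test_that("sweep and pair constructors enforce their invariants", {
  expect_error(sweep_record(rep(0, 100), -1, 1), "sampling_rate")
  expect_error(sweep_record(rep(0, 100), 20000, 500), "outside sweep")
  expect_error(sweep_record(rep(0, 2000), 20000, 50, ap_time = 40),
               "precedes")
  sw1 <- flat_sweep()
  sw2 <- sweep_record(rep(0, 2000), 10000, 50)
  expect_error(pair_recording("p", list(sw1, sw2)), "sampling_rate")
  expect_error(time_window(5, 5))
})

test_that("archive round-trips bit-exactly and preserves counts", {
  sims <- lapply(1:3, function(i)
    simulate_pair(synth_pair_config(n_trials = 8, sweep_ms = 80, pre_ms = 30,
                                    pair_id = paste0("p", i), seed = i)))
  pairs <- lapply(sims, `[[`, "pair")
  dir <- tempfile("arch_")
  write_pair_archive(pairs, dir)
  back <- read_pair_archive(dir)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$pair_id, pairs[[i]]$pair_id)
    expect_identical(back[[i]]$phenotype, pairs[[i]]$phenotype)
    expect_length(back[[i]]$sweeps, 8)
    for (j in 1:8) {
      expect_identical(back[[i]]$sweeps[[j]]$samples,
                       pairs[[i]]$sweeps[[j]]$samples)
      expect_identical(back[[i]]$sweeps[[j]]$ap_time,
                       pairs[[i]]$sweeps[[j]]$ap_time)
      expect_identical(back[[i]]$sweeps[[j]]$labels,
                       pairs[[i]]$sweeps[[j]]$labels)
    }
  }
  # guards
  expect_error(write_pair_archive(list(), tempfile()), "non-empty")
  expect_error(write_pair_archive(pairs, dir), "overwrite")
  expect_silent(write_pair_archive(pairs[1], dir, overwrite = TRUE))
})

test_that("archive without phenotype falls back to unknown with a warning", {
  sim <- simulate_pair(synth_pair_config(n_trials = 4, sweep_ms = 60,
                                         pre_ms = 30, seed = 1))
  dir <- tempfile("arch_")
  write_pair_archive(list(sim$pair), dir)
  man <- read.csv(file.path(dir, "manifest.csv"))
  man$phenotype <- NULL
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  expect_warning(back <- read_pair_archive(dir), "phenotype")
  expect_identical(back[[1]]$phenotype, "unknown")
})

test_that("segment_train counts, re-references and conserves samples", {
  fs <- 20000
  n <- 10 * fs                      # 10 s
  stim_times <- seq(0, 9900, by = 100)
  sweeps <- segment_train(rep(0, n), fs, stim_times, c(0, 100))
  expect_length(sweeps, 100)
  expect_true(all(vapply(sweeps, function(s) length(s$samples), 0L) == 2000))
  expect_equal(sum(vapply(sweeps, function(s) length(s$samples), 0L)),
               n)                    # no overlap, no gap
  expect_true(all(vapply(sweeps, function(s) all(s$samples == 0), TRUE)))
  expect_error(segment_train(rep(0, n), fs, stim_times, c(0, 150)),
               "longer than")
})

test_that("segmented synthetic train carries one event at fixed latency", {
  cfg <- synth_timecourse_config(duration_min = 0.5, rundown_rate = 0,
                                 drug = "none", amplitude_cv = 0,
                                 noise_sd = 0, sampling_rate = 10000,
                                 seed = 9)
  tc <- simulate_timecourse(cfg)
  sweeps <- segment_train(tc$samples, tc$sampling_rate, tc$stim_times,
                          c(-10, 90))
  peaks <- vapply(sweeps[5:60], function(s)
    peak_and_delay(s, ap_time = s$stim_time)$peak_time - s$stim_time, 0)
  expect_lt(diff(range(peaks)), 0.21)       # fixed latency, one event
  expect_gt(min(vapply(sweeps[5:60], function(s)
    peak_and_delay(s, ap_time = s$stim_time)$peak_amp, 0)), 30)
})

test_that("AP detection finds synthetic spikes and rejects pure noise", {
  lp <- simulate_loose_patch(n_trials = 100, p_ap = 0.62, spike_latency = 3,
                             amp = 50, noise_sd = 5, seed = 23)
  det <- vapply(lp$sweeps, function(s) detect_ap_time(s), 0)
  hit <- !is.na(det)
  expect_identical(hit, lp$truth$ap)        # no misses, no false alarms
  err <- det[hit] - lp$truth$spike_time[hit]
  expect_lt(max(abs(err)), 0.1)
  # detected rate within the binomial 95% CI of the 0.62 spike rate
  ci <- qbinom(c(0.025, 0.975), 100, 0.62)
  expect_gte(sum(hit), ci[1])
  expect_lte(sum(hit), ci[2])
  expect_error(detect_ap_time(lp$sweeps[[1]], search = c(20, 20.5)),
               "shorter than 1 ms")
})

test_that("AP detection false-positive rate on pure noise is below 1%", {
  lp <- simulate_loose_patch(n_trials = 400, p_ap = 0, noise_sd = 5,
                             seed = 22)
  det <- vapply(lp$sweeps, function(s) detect_ap_time(s), 0)
  expect_lte(mean(!is.na(det)), 0.01)
})
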