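# End-to-end driver: simulate (optional) -> per-pair analysis -> population
# statistics -> report files. Configuration is a plain list (or a YAML file
# with the same structure); every randomness source derives from one seed.

pipeline_defaults <- function() {
  list(seed = 1,
       output_dir = NULL,
       input_archive = NULL,      # analyse an existing archive instead
       simulate = list(n_glyt2_pos = 28, n_glyt2_neg = 10, n_unconnected = 2,
                       n_trials = 60, sweep_ms = 500, sampling_rate = 20000,
                       noise_sd = 5),
       analysis = list(alpha = 0.05, n_baseline_draws = 1000),
       stats = list(n_reps = 10000, n_draws = 10))
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(user[[k]]) && is.list(defaults[[k]]))
      merge_config(defaults[[k]], user[[k]]) else user[[k]]
  }
  defaults
}

# draw per-pair generating parameters emulating the two phenotypes:
# GlyT2- pairs have ~1.73-fold larger amplitudes, a larger slow-decay
# fraction and slow charge, and a bimodal failure-rate distribution
# (either negligible or high); GlyT2+ failure rates form one continuum.
sample_pair_config <- function(phenotype, connected, sim, pair_id) {
  base_amp <- 55 * stats::rlnorm(1, -0.5 * log(1 + 0.45^2),
                                 sqrt(log(1 + 0.45^2)))
  if (phenotype == "GlyT2_neg") {
    amp <- base_amp * 1.73
    a2f <- 0.28
    q_slow <- 0.88
    p_fail <- if (stats::runif(1) < 0.7) stats::runif(1, 0, 0.05)
              else stats::runif(1, 0.3, 0.55)
  } else {
    amp <- base_amp
    a2f <- 0.22
    q_slow <- 0.49
    p_fail <- stats::rbeta(1, 1.1, 4.5)
  }
  synth_pair_config(
    connected = connected, n_trials = sim$n_trials,
    p_fail = if (connected) p_fail else 0,
    phasic_params = list(A1 = amp * (1 - a2f), TAU1 = 2,
                         A2 = amp * a2f, TAU2 = 16.5, rise_tau = 0.3),
    delayed_params = list(A = amp * 0.2, TAU = 10, onset_shift = 0.5,
                          rise_tau = 1.5),
    spillover_params = list(q_slow = q_slow, tau_slow = 359, rise_tau = 5,
                            fail_fraction = 1 / 3, unconnected_fraction = 0.18),
    noise_sd = sim$noise_sd, sweep_ms = sim$sweep_ms,
    sampling_rate = sim$sampling_rate, phenotype = phenotype,
    pair_id = pair_id, seed = sample.int(.Machine$integer.max, 1))
}

#' Simulate a full two-phenotype study population
#'
#' Generates connected GlyT2+ and GlyT2- pairs plus unconnected extras with
#' per-pair parameter variability emulating the population structure of the
#' recorded data (scaled amplitude/charge distributions, bimodal GlyT2-
#' failure rates).
#'
#' @param sim simulation settings (see `pipeline_defaults()$simulate`).
#' @param seed integer seed (local).
#' @return list of `simulate_pair()` results.
#' @export
simulate_population <- function(sim = pipeline_defaults()$simulate, seed = 1) {
  sim <- merge_config(pipeline_defaults()$simulate, sim)
  with_seed(seed, {
    cfgs <- c(
      lapply(seq_len(sim$n_glyt2_pos), function(i)
        sample_pair_config("GlyT2_pos", TRUE, sim, sprintf("pos_%02d", i))),
      lapply(seq_len(sim$n_glyt2_neg), function(i)
        sample_pair_config("GlyT2_neg", TRUE, sim, sprintf("neg_%02d", i))),
      lapply(seq_len(sim$n_unconnected), function(i)
        sample_pair_config(if (i %% 2) "GlyT2_pos" else "GlyT2_neg", FALSE,
                           sim, sprintf("unc_%02d", i))))
    lapply(cfgs, simulate_pair)
  })
}

#' Run the end-to-end pipeline
#'
#' Simulates (or loads) a set of pair recordings, analyses every pair
#' ([analyze_pair()]), assembles the population summary table and computes
#' the group-statistics battery: Mann-Whitney phenotype contrasts and
#' Conover variance tests on the key per-pair metrics, plus the two-cluster
#' K-means / bootstrap inertia bimodality analysis of the failure rates.
#' When `output_dir` is set, writes `trial_metrics.csv`, `pair_summary.csv`,
#' `stats.json` and a run `manifest.json` (config, seed, package version).
#'
#' @param config a configuration list or path to a YAML file; unspecified
#'   entries take the defaults of `pipeline_defaults()`.
#' @return list with `pairs` (analyses), `summary` (per-pair data.frame),
#'   `stats` (list of test results) and `config`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(pipeline_defaults(), config)

  if (!is.null(cfg$input_archive)) {
    if (!dir.exists(cfg$input_archive))
      stopf("input archive '%s' not found", cfg$input_archive)
    pairs <- read_pair_archive(cfg$input_archive)
  } else {
    pairs <- lapply(simulate_population(cfg$simulate, seed = cfg$seed),
                    `[[`, "pair")
  }

  analyses <- with_seed(cfg$seed + 1L, lapply(pairs, function(p)
    analyze_pair(p, alpha = cfg$analysis$alpha,
                 n_baseline_draws = cfg$analysis$n_baseline_draws,
                 seed = sample.int(.Machine$integer.max, 1))))
  summary <- do.call(rbind, lapply(analyses, pair_summary))
  trials <- do.call(rbind, lapply(analyses, function(a) {
    cbind(pair_id = a$summary$pair_id, a$trials)
  }))

  conn <- summary[summary$connected %in% TRUE, , drop = FALSE]
  by_ph <- function(col) {
    v <- conn[[col]]
    list(pos = v[conn$phenotype == "GlyT2_pos" & is.finite(v)],
         neg = v[conn$phenotype == "GlyT2_neg" & is.finite(v)])
  }
  stats_out <- list()
  for (metric in c("I_AP_pos", "Q_AP_pos", "weighted_tau_ms", "p_fail",
                   "Q_slow_ap_pos", "delay_ms", "Q_delayed",
                   "q_delayed_over_i_phasic_ms")) {
    g <- by_ph(metric)
    if (length(g$pos) >= 3 && length(g$neg) >= 3) {
      stats_out[[paste0(metric, "_mw")]] <- group_compare(g$neg, g$pos)
      if (length(g$pos) >= 5 && length(g$neg) >= 5)
        stats_out[[paste0(metric, "_conover")]] <-
          conover_variance_test(g$neg, g$pos)
    }
  }
  g <- by_ph("p_fail")
  if (length(g$pos) >= 4 && length(g$neg) >= 4) {
    stats_out$p_fail_kmeans_neg <- kmeans_1d_k2(g$neg)
    stats_out$p_fail_kmeans_pos <- kmeans_1d_k2(g$pos)
    stats_out$p_fail_bimodality <- bootstrap_bimodality(
      g$pos, g$neg, n_draws = cfg$stats$n_draws,
      n_reps = cfg$stats$n_reps, seed = cfg$seed + 2L)
  }

  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(trials, file.path(cfg$output_dir, "trial_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(cfg$output_dir, "pair_summary.csv"),
                     row.names = FALSE)
    stats_json <- lapply(stats_out, function(s)
      s[setdiff(names(s), c("bootstrap_inertias", "assignment"))])
    jsonlite::write_json(stats_json,
                         file.path(cfg$output_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest <- list(config = cfg, seed = cfg$seed,
                     package_version =
                       as.character(utils::packageVersion("ipsckit")),
                     n_pairs = length(pairs), timestamped = FALSE)
    jsonlite::write_json(manifest,
                         file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(pairs = analyses, summary = summary, trials = trials,
       stats = stats_out, config = cfg)
}

#' Build a small deterministic fixture archive
#'
#' Writes a three-pair synthetic archive (one connected pair per phenotype
#' plus one unconnected pair) together with per-pair ground-truth CSVs.
#' Regeneration under the same seed is byte-identical.
#'
#' @param seed integer seed.
#' @param dir target directory (created; must not exist unless `overwrite`).
#' @param overwrite overwrite an existing fixture directory.
#' @param n_trials trials per pair.
#' @param sweep_ms sweep duration in ms.
#' @return `dir`, invisibly.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("ipsc_fixture_"),
                          overwrite = FALSE, n_trials = 20, sweep_ms = 120,
                          sampling_rate = 10000) {
  sims <- with_seed(seed, {
    mk <- function(pair_id, phenotype, connected, s)
      simulate_pair(synth_pair_config(
        connected = connected, n_trials = n_trials, sweep_ms = sweep_ms,
        sampling_rate = sampling_rate,
        phenotype = phenotype, pair_id = pair_id, seed = s))
    list(mk("fix_pos", "GlyT2_pos", TRUE, seed + 11L),
         mk("fix_neg", "GlyT2_neg", TRUE, seed + 12L),
         mk("fix_unc", "GlyT2_pos", FALSE, seed + 13L))
  })
  write_pair_archive(lapply(sims, `[[`, "pair"), dir, overwrite = overwrite)
  for (s in sims) {
    tr <- s$truth$trials
    num <- vapply(tr, is.numeric, TRUE)
    tr[num] <- lapply(tr[num], function(x) fmt17(x))
    utils::write.csv(tr, file.path(dir, sprintf("truth_%s.csv",
                                                s$pair$pair_id)),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
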