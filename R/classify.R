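#' Connectivity classification from charge distributions
#'
#' Compares the post-AP trial-charge distribution with the pre-stimulus
#' baseline null by a two-sample Kolmogorov-Smirnov test. A pair is called
#' connected when the distributions differ at level `alpha` *and* the
#' post-AP mean charge exceeds the baseline mean (a right-shift guard: IPSCs
#' can only add inward charge).
#'
#' @param post_ap_charges trial charges (pC) from AP-success trials.
#' @param baseline_charges charges from [baseline_charge_distribution()].
#' @param alpha significance level (default 0.05).
#' @param pair_id optional identifier carried into the result.
#' @return list of class `connectivity_result`: `ks_statistic`, `ks_p`,
#'   `connected`, `n_post_ap`, `n_baseline`, `pair_id`.
#' @export
classify_connectivity <- function(post_ap_charges, baseline_charges,
                                  alpha = 0.05, pair_id = NA_character_) {
  if (length(post_ap_charges) < 10 || length(baseline_charges) < 10)
    stopf("need >= 10 charges in each sample")
  kt <- suppressWarnings(stats::ks.test(post_ap_charges, baseline_charges))
  connected <- kt$p.value < alpha &&
    mean(post_ap_charges) > mean(baseline_charges)
  structure(list(pair_id = pair_id,
                 ks_statistic = unname(kt$statistic), ks_p = kt$p.value,
                 connected = connected,
                 n_post_ap = length(post_ap_charges),
                 n_baseline = length(baseline_charges)),
            class = "connectivity_result")
}

#' Transmission failure rate from the symmetry of the failure charge null
#'
#' Failure trials carry no synaptic charge, so their measured charges are
#' symmetric about zero (as the baseline null). The failure count is
#' estimated as twice the number of trials with *negative* reported charge
#' (outward current), and the failure threshold is the corresponding order
#' statistic of the charge distribution; trials with charge at or below the
#' threshold are labelled failures (ties count as failures, keeping the
#' estimate conservative).
#'
#' @param post_ap_charges trial charges in pC (reported-positive convention:
#'   outward current gives negative charge).
#' @return list of class `failure_result`: `p_fail`, `threshold_charge`,
#'   `failure_trials` (indices into the input), `n_fail`, `n`.
#' @export
failure_rate <- function(post_ap_charges) {
  n <- length(post_ap_charges)
  if (!n) stopf("empty charge vector")
  n_neg <- sum(post_ap_charges < 0)
  n_fail <- 2L * n_neg
  if (n_fail > n) {
    warnf("more than half the charges are negative; capping p_fail at 1")
    n_fail <- n
  }
  if (n_fail == 0L) {
    return(structure(list(p_fail = 0, threshold_charge = -Inf,
                          failure_trials = integer(0), n_fail = 0L, n = n),
                     class = "failure_result"))
  }
  thr <- sort(post_ap_charges)[n_fail]
  structure(list(p_fail = n_fail / n, threshold_charge = thr,
                 failure_trials = which(post_ap_charges <= thr),
                 n_fail = n_fail, n = n),
            class = "failure_result")
}

# sliding-difference statistic over all sample times of a trace.
# D(t) = mean(raw current over [t-10.3, t-0.3)) - mean(raw over [t, t+0.5)),
# i.e. local baseline minus the short leading window, the two separated by
# 0.3 ms (the rise time of a classical fast IPSC). The onset of a fast,
# negative-going IPSC yields a positive maximum of D.
slide_statistic <- function(samples, sampling_rate) {
  fs <- sampling_rate
  w_long <- as.integer(round(10 * fs / 1000))
  w_short <- as.integer(round(0.5 * fs / 1000))
  gap <- as.integer(round(0.3 * fs / 1000))
  cs <- c(0, cumsum(samples))
  n <- length(samples)
  mean_win <- function(i0, i1) {
    i0 <- pmin(pmax(i0, 1L), n)
    i1 <- pmin(pmax(i1, 1L), n)
    (cs[i1 + 1L] - cs[i0]) / pmax(i1 - i0 + 1L, 1L)
  }
  idx <- seq_len(n)
  long_mean <- mean_win(idx - gap - w_long, idx - gap - 1L)
  short_mean <- mean_win(idx, idx + w_short - 1L)
  d <- long_mean - short_mean
  d[idx - gap - w_long < 1L | idx + w_short - 1L > n] <- NA_real_
  d
}

# null statistics of the slide statistic over the pre-stimulus region of a
# sweep. With max_window_ms set, the tabulated statistic is the maximum of D
# over consecutive non-overlapping windows of that width — the same
# statistic the phasic test applies to its jitter window, so the
# baseline + 2SD threshold refers to a like-for-like null.
slide_baseline_stats <- function(sweep, max_window_ms = NULL) {
  fs <- sweep$sampling_rate
  d <- slide_statistic(sweep$samples, fs)
  i0 <- ms_to_index(10.5, fs)
  i1 <- ms_to_index(max(sweep$stim_time - 1, 11.5), fs)
  seg <- d[i0:i1]
  if (!is.null(max_window_ms)) {
    w <- max(2L, as.integer(round(max_window_ms * fs / 1000)))
    n_win <- length(seg) %/% w
    if (n_win >= 3L) {
      seg <- vapply(seq_len(n_win), function(k)
        max(seg[((k - 1L) * w + 1L):(k * w)], na.rm = TRUE), 0)
    }
  }
  seg <- seg[is.finite(seg)]
  list(mean = mean(seg), sd = stats::sd(seg))
}

#' Fast-component rising time of a pair
#'
#' Locates the rise of the fast IPSC component on the mean success trace as
#' the time maximising the absolute sliding-difference statistic within
#' 6 ms of the spike. Pairs whose maximum does not exceed the pre-stimulus
#' statistic mean + 2 SD are flagged as having no detectable fast component.
#'
#' @param mean_trace averaged success [sweep_record].
#' @param ap_time spike time in ms.
#' @return list of class `fast_rise_result`: `time` (ms), `stat_max`,
#'   `baseline_mean`, `baseline_sd`, `undetermined`.
#' @export
fast_rise_time <- function(mean_trace, ap_time = mean_trace$ap_time) {
  fs <- mean_trace$sampling_rate
  if (is.na(ap_time)) stopf("fast_rise_time requires an AP time")
  d <- slide_statistic(mean_trace$samples, fs)
  i0 <- ms_to_index(ap_time, fs)
  i1 <- ms_to_index(ap_time + 6, fs) - 1L
  if (i1 > length(d) || i0 < 1L) stopf("insufficient samples for the windows")
  seg <- d[i0:i1]
  if (all(!is.finite(seg)) || all(seg == 0, na.rm = TRUE)) {
    return(structure(list(time = NA_real_, stat_max = 0,
                          baseline_mean = NA_real_, baseline_sd = NA_real_,
                          undetermined = TRUE), class = "fast_rise_result"))
  }
  bl <- slide_baseline_stats(mean_trace)
  imax <- which.max(abs(seg))
  structure(list(time = index_to_ms(i0 - 1L + imax, fs),
                 stat_max = seg[imax],
                 baseline_mean = bl$mean, baseline_sd = bl$sd,
                 undetermined = abs(seg[imax]) <= bl$mean + 2 * bl$sd),
            class = "fast_rise_result")
}

#' Classify transmission successes as phasic or delayed
#'
#' A success is phasic when its sliding-difference statistic, maximised
#' within a ±0.5 ms jitter window around the pair's fast-component rising
#' time, exceeds that trial's pre-stimulus statistic mean + 2 SD; otherwise
#' it lacks the fast-rising fast-decaying component and is classed delayed.
#'
#' @param sweeps list of success-trial [sweep_record] objects.
#' @param rise_time the pair's fast-component rising time (ms), from
#'   [fast_rise_time()] (a `fast_rise_result` is also accepted).
#' @param baseline_stats optional list `mean`, `sd` of the slide statistic
#'   under the null; by default estimated per trial from its own
#'   pre-stimulus segment.
#' @return list of class `event_class_result`: `event_class` (character per
#'   trial), `slide_stat` (max statistic per trial), `rise_time`.
#' @export
classify_phasic_delayed <- function(sweeps, rise_time, baseline_stats = NULL) {
  if (inherits(rise_time, "fast_rise_result")) rise_time <- rise_time$time
  if (is.na(rise_time)) stopf("rise_time is undefined")
  if (inherits(sweeps, "sweep_record")) sweeps <- list(sweeps)
  stat <- numeric(length(sweeps))
  cls <- character(length(sweeps))
  for (i in seq_along(sweeps)) {
    sw <- sweeps[[i]]
    fs <- sw$sampling_rate
    d <- slide_statistic(sw$samples, fs)
    i0 <- ms_to_index(rise_time - 0.5, fs)
    i1 <- ms_to_index(rise_time + 0.5, fs)
    seg <- d[max(1L, i0):min(length(d), i1)]
    stat[i] <- max(seg, na.rm = TRUE)
    bl <- baseline_stats %||% slide_baseline_stats(sw, max_window_ms = 1)
    if (is.null(bl$mean) || is.null(bl$sd)) stopf("missing baseline stats")
    cls[i] <- if (stat[i] > bl$mean + 2 * bl$sd) "phasic" else "delayed"
  }
  structure(list(event_class = cls, slide_stat = stat, rise_time = rise_time),
            class = "event_class_result")
}
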