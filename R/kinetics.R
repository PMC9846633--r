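# Exponential decomposition of averaged IPSC decays. All fits act on the
# sign-inverted, baseline-zeroed current (reported-positive convention) and
# start at the empirical peak: the rise is excluded, only the decay is
# modelled. Initialisation is deterministic (tail log-linear regression for
# the slow time constant, half-decay time for the fast one, linear least
# squares for amplitudes) so that identical input yields identical output.

# extract the reported-positive decay segment [t_start, t_end) of a sweep,
# baseline-zeroed on the 10 ms before `base_ref` (default: stim_time)
decay_segment <- function(sweep, t_start, t_end, base_ref = NULL) {
  fs <- sweep$sampling_rate
  base_ref <- base_ref %||% sweep$stim_time
  ib0 <- max(1L, ms_to_index(base_ref - 10, fs))
  ib1 <- max(ib0 + 1L, ms_to_index(base_ref, fs) - 1L)
  base <- mean(sweep$samples[ib0:ib1])
  i0 <- ms_to_index(t_start, fs)
  i1 <- min(length(sweep$samples), ms_to_index(t_end, fs) - 1L)
  if (i1 - i0 < 10L) stopf("decay window too short")
  list(t = index_to_ms(i0:i1, fs) - index_to_ms(i0, fs),
       y = -(sweep$samples[i0:i1] - base))
}

decay_fit_failure <- function(model, n) {
  structure(list(A1 = NaN, TAU1 = NaN, A2 = NaN, TAU2 = NaN,
                 a2_fraction = NaN, q_fit = NaN, weighted_tau_fit = NaN,
                 rss = NaN, converged = FALSE, model = model, n = n),
            class = "decay_fit")
}

make_decay_fit <- function(A1, TAU1, A2, TAU2, rss, converged, model, n) {
  if (!is.na(TAU1) && !is.na(TAU2) && TAU2 < TAU1) { # order: TAU1 < TAU2
    tmp <- c(A1, TAU1); A1 <- A2; TAU1 <- TAU2; A2 <- tmp[1]; TAU2 <- tmp[2]
  }
  structure(list(A1 = A1, TAU1 = TAU1, A2 = A2, TAU2 = TAU2,
                 a2_fraction = if (A1 + A2 > 0) A2 / (A1 + A2) else NaN,
                 q_fit = (A1 * TAU1 + A2 * TAU2) / 1000,
                 weighted_tau_fit = if (A1 + A2 > 0)
                   (A1 * TAU1 + A2 * TAU2) / (A1 + A2) else NaN,
                 rss = rss, converged = converged, model = model, n = n),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(paste0("<decay_fit:%s> A1 = %.2f pA, TAU1 = %.2f ms, ",
                     "A2 = %.2f pA, TAU2 = %.2f ms, Q = %.3f pC%s\n"),
              x$model, x$A1, x$TAU1, x$A2, x$TAU2, x$q_fit,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# deterministic initial estimates for a (bi-)exponential decay
init_decay <- function(t, y, biexp = TRUE) {
  y0 <- max(mean(y[seq_len(min(5L, length(y)))]), .Machine$double.eps)
  span <- t[length(t)]
  tail_i <- which(t > 0.45 * span & y > y0 * 1e-3)
  tau2 <- if (length(tail_i) >= 5L) {
    sl <- stats::coef(stats::lm(log(y[tail_i]) ~ t[tail_i]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else span / 5
  } else span / 5
  tau2 <- min(max(tau2, 0.5), 5 * span)
  ihalf <- which(y < 0.5 * y0)[1L]
  tau1 <- if (!is.na(ihalf)) t[ihalf] / log(2) else tau2 / 8
  tau1 <- min(max(tau1, 0.05), tau2 / 3)
  if (!biexp) return(list(tau = max(tau1, tau2 / 4)))
  e1 <- exp(-t / tau1); e2 <- exp(-t / tau2)
  amps <- tryCatch(stats::coef(stats::lm(y ~ 0 + e1 + e2)),
                   error = function(e) c(y0 * 0.7, y0 * 0.3))
  amps[!is.finite(amps) | amps < 0] <- y0 * 0.1
  list(A1 = amps[[1L]], tau1 = tau1, A2 = amps[[2L]], tau2 = tau2)
}

#' Bi-exponential fit of an averaged IPSC decay
#'
#' Fits `A1*exp(-t/TAU1) + A2*exp(-t/TAU2)` to the sign-inverted,
#' baseline-zeroed current from `t_start` (normally the IPSC peak) to
#' `t_end`. The derived charge is `q_fit = (A1*TAU1 + A2*TAU2)/1000` pC and
#' the fit-based weighted decay constant `(A1*TAU1 + A2*TAU2)/(A1 + A2)` ms.
#' When the two fitted time constants collapse to within 10% of each other,
#' the decay is refit as a single exponential and the result is flagged
#' `model = "mono_fallback"`. A non-negative constant pedestal is fitted
#' alongside the exponentials (`offset = TRUE`) so the slow spillover tail,
#' quasi-constant on this time scale, does not inflate the fast time
#' constants; the pedestal is excluded from the derived charge.
#'
#' @param sweep averaged [sweep_record] (raw sign).
#' @param t_start,t_end fit window in sweep time (ms); `t_start` should be
#'   the empirical peak time.
#' @param base_ref reference for baseline zeroing (default: stimulus time).
#' @param offset fit a constant pedestal term (default `TRUE`).
#' @return object of class `decay_fit`.
#' @export
# attempt nlsLM over a fixed ladder of start values; the ladder keeps the
# fit deterministic while riding out pivoted-QR singularities that single
# start points occasionally hit
try_nlsLM <- function(formula, data, starts, lower) {
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) return(fit)
  }
  NULL
}

fit_biexponential <- function(sweep, t_start, t_end, base_ref = NULL,
                              offset = TRUE) {
  seg <- decay_segment(sweep, t_start, t_end, base_ref)
  t <- seg$t; y <- seg$y
  ini <- init_decay(t, y, biexp = TRUE)
  ini_b <- ini
  ini_b$tau1 <- ini$tau1 * 0.7
  ini_b$tau2 <- ini$tau2 * 1.3
  fit <- if (offset) {
    try_nlsLM(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2) + C, seg,
              list(c(ini, list(C = max(min(y), 1e-3))),
                   c(ini, list(C = 0.1)),
                   c(ini_b, list(C = max(0.1 * stats::median(y), 0.1)))),
              lower = c(0, 0.01, 0, 0.01, 0))
  } else {
    try_nlsLM(y ~ A1 * exp(-t / tau1) + A2 * exp(-t / tau2), seg,
              list(ini, ini_b), lower = c(0, 0.01, 0, 0.01))
  }
  if (is.null(fit)) return(decay_fit_failure("biexp", length(y)))
  cf <- stats::coef(fit)
  taus <- sort(c(cf[["tau1"]], cf[["tau2"]]))
  a2f <- cf[["A2"]] / max(cf[["A1"]] + cf[["A2"]], .Machine$double.eps)
  if (taus[2L] / taus[1L] < 1.1 || a2f < 0.01 || a2f > 0.99) {
    mono <- fit_mono_segment(t, y, offset = offset)
    return(make_decay_fit(mono$A, mono$TAU, 0, mono$TAU, mono$rss,
                          mono$converged, "mono_fallback", length(y)))
  }
  make_decay_fit(cf[["A1"]], cf[["tau1"]], cf[["A2"]], cf[["tau2"]],
                 sum(stats::resid(fit)^2), TRUE, "biexp", length(y))
}

fit_mono_segment <- function(t, y, offset = TRUE) {
  ini <- init_decay(t, y, biexp = FALSE)
  A0 <- max(y[1L], .Machine$double.eps)
  fit <- if (offset) {
    try_nlsLM(y ~ A * exp(-t / tau) + C, data.frame(t = t, y = y),
              list(list(A = A0, tau = ini$tau, C = max(min(y), 1e-3)),
                   list(A = A0, tau = ini$tau, C = 0.1),
                   list(A = A0, tau = ini$tau * 0.6, C = 0.1)),
              lower = c(0, 0.01, 0))
  } else {
    try_nlsLM(y ~ A * exp(-t / tau), data.frame(t = t, y = y),
              list(list(A = A0, tau = ini$tau),
                   list(A = A0, tau = ini$tau * 0.6)),
              lower = c(0, 0.01))
  }
  if (is.null(fit))
    return(list(A = NaN, TAU = NaN, rss = NaN, converged = FALSE))
  cf <- stats::coef(fit)
  list(A = cf[["A"]], TAU = cf[["tau"]], rss = sum(stats::resid(fit)^2),
       converged = TRUE)
}

#' Mono-exponential fit of an averaged delayed-IPSC decay
#'
#' As [fit_biexponential()] with a single component
#' `A*exp(-t/TAU)`; used for delayed IPSCs, which lack the fast-rising
#' fast-decaying component. Pairs with fewer than `min_events` contributing
#' delayed trials cannot be fitted reliably and are refused (flagged
#' non-converged with model `"too_few_events"`).
#'
#' @inheritParams fit_biexponential
#' @param n_events number of trials averaged into `sweep` (optional guard).
#' @param min_events minimum events required (default 5).
#' @return object of class `decay_fit` with `A2 = 0`.
#' @export
fit_monoexponential <- function(sweep, t_start, t_end, base_ref = NULL,
                                n_events = NULL, min_events = 5,
                                offset = TRUE) {
  if (!is.null(n_events) && n_events < min_events)
    return(decay_fit_failure("too_few_events", n_events))
  seg <- decay_segment(sweep, t_start, t_end, base_ref)
  mono <- fit_mono_segment(seg$t, seg$y, offset = offset)
  make_decay_fit(mono$A, mono$TAU, 0, mono$TAU, mono$rss, mono$converged,
                 "mono", length(seg$y))
}

#' Weighted decay time constant from charge and peak
#'
#' The charge-to-peak ratio `Q/I` of an IPSC is a fit-free summary of its
#' decay kinetics: for an instantaneous-rise multi-exponential decay it
#' equals the amplitude-weighted mean of the time constants.
#'
#' @param q charge in pC.
#' @param peak peak amplitude in pA (positive magnitude).
#' @return weighted decay time constant in ms (`1000 * q / peak`).
#' @export
weighted_tau <- function(q, peak) {
  if (!is.finite(peak) || peak <= 0) stopf("peak must be > 0")
  1000 * q / peak
}

#' Slow spillover component from the cumulative charge
#'
#' In `"cumsum"` mode the cumulative time-integral of the sign-inverted mean
#' AP-success trace is fitted, from 50 ms after the IPSC peak, with the
#' saturating form `C(t) = C0 + b*(t - t0) + Q*(1 - exp(-(t - t0)/tau_slow))`;
#' the linear term absorbs any residual DC error of the 10-ms local baseline,
#' which would otherwise accumulate over the seconds-long window and bias the
#' fit. The reported `q_slow` extrapolates the fitted exponential tail back
#' to the peak time (`Q * exp(50/tau_slow)`), so it measures the full slow
#' charge of the IPSC. In `"tail36"` mode the slow charge is obtained by direct
#' integration from 36 ms after the peak ([slow_charge()]); no time constant
#' is estimated. Horizons shorter than 1 s after the peak fall back from
#' `"cumsum"` to `"tail36"` with a warning.
#'
#' @param sweep averaged [sweep_record].
#' @param ap_time spike time (ms).
#' @param mode `"cumsum"` or `"tail36"`.
#' @param horizon [time_window]; default `[ap_time, min(ap_time + 2000, end)]`.
#' @return list of class `slow_component`: `q_slow` (pC), `tau_slow` (ms,
#'   `NA` in tail36 mode), `mode`, `fit_window`, `converged`.
#' @export
fit_slow_component <- function(sweep, ap_time = sweep$ap_time,
                               mode = c("cumsum", "tail36"), horizon = NULL) {
  mode <- match.arg(mode)
  fs <- sweep$sampling_rate
  dur <- sweep_duration_ms(sweep)
  horizon <- if (is.null(horizon)) time_window(ap_time, min(ap_time + 2000, dur))
  else as_time_window(horizon)
  if (horizon$end > dur + 1e-9) stopf("horizon extends beyond the sweep")
  pk <- peak_and_delay(sweep, ap_time)
  if (mode == "cumsum" && horizon$end - pk$peak_time < 1000) {
    warnf("horizon < 1 s beyond the peak; falling back to tail36 mode")
    mode <- "tail36"
  }
  if (mode == "tail36") {
    q <- slow_charge(sweep, ap_time, horizon, peak_time = pk$peak_time)
    return(structure(list(q_slow = q, tau_slow = NA_real_, mode = "tail36",
                          fit_window = c(pk$peak_time + 36, horizon$end),
                          converged = TRUE), class = "slow_component"))
  }
  ib0 <- max(1L, ms_to_index(ap_time - 10, fs))
  ib1 <- max(ib0 + 1L, ms_to_index(ap_time, fs) - 1L)
  base <- mean(sweep$samples[ib0:ib1])
  y <- -(sweep$samples - base)
  ia <- ms_to_index(ap_time, fs)
  ie <- min(length(y), ms_to_index(horizon$end, fs))
  dt <- 1000 / fs
  cum <- c(0, cumsum((y[ia:(ie - 1L)] + y[(ia + 1L):ie]) / 2 * dt)) / 1000
  tms <- index_to_ms(ia:ie, fs)
  t0 <- pk$peak_time + 50
  sel <- tms >= t0
  tt <- tms[sel] - t0
  cc <- cum[sel]
  qs0 <- max(cc[length(cc)] - cc[1L], 1e-4)
  fit <- tryCatch(
    minpack.lm::nlsLM(cc ~ C0 + b * tt + Q * (1 - exp(-tt / tau)),
                      start = list(C0 = cc[1L], b = 0, Q = qs0, tau = 300),
                      lower = c(-Inf, -Inf, 0, 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(q_slow = NaN, tau_slow = NaN, mode = "cumsum",
                          fit_window = c(t0, horizon$end), converged = FALSE),
                     class = "slow_component"))
  }
  cf <- stats::coef(fit)
  tau <- cf[["tau"]]
  structure(list(q_slow = cf[["Q"]] * exp(50 / tau), tau_slow = tau,
                 mode = "cumsum", fit_window = c(t0, horizon$end),
                 converged = tau > 50), class = "slow_component")
}
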