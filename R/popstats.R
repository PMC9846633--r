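# Population statistics. Rank-based comparisons delegate to the standard
# routines; the Conover squared-ranks variance test, the exact 1-D
# two-cluster K-means and the bootstrap inertia bimodality test are
# implemented here.

stat_result <- function(test_name, statistic, p_value, n, two_sided = TRUE,
                        ...) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   p_value = unname(p_value), n = n, two_sided = two_sided),
              list(...)),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)%s\n", x$test_name,
              x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Two-sided rank comparison of two groups
#'
#' Bilateral non-parametric Mann-Whitney test for independent groups, or the
#' Wilcoxon signed-rank test for paired data (normal approximation with
#' continuity correction, so results are deterministic with ties).
#'
#' @param x,y numeric samples (equal length when `paired`).
#' @param paired logical.
#' @return a `stat_result` with `test_name`, `statistic`, `p_value`, `n`.
#' @export
group_compare <- function(x, y, paired = FALSE) {
  if (length(x) < 3 || length(y) < 3) stopf("need >= 3 values per group")
  if (paired && length(x) != length(y))
    stopf("paired comparison requires equal lengths")
  if (paired && all(x == y)) {
    return(stat_result("wilcoxon_signed_rank", NA_real_, NA_real_,
                       length(x), note = "all paired differences zero"))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired,
                                            exact = FALSE, correct = TRUE))
  stat_result(if (paired) "wilcoxon_signed_rank" else "mann_whitney",
              wt$statistic, wt$p.value, c(length(x), length(y)))
}

#' Conover squared-ranks test of equal variance
#'
#' Nonparametric test of dispersion: absolute deviations from the group
#' means are ranked jointly, the ranks are squared, and the sum over the
#' first group is compared with its null expectation using the
#' tie-corrected normal approximation (two-sided). A permutation mode is
#' available for small samples.
#'
#' @param x,y numeric samples (n >= 5 each).
#' @param method `"normal"` (default) or `"permutation"`.
#' @param n_perm permutation count for the permutation mode.
#' @param seed optional seed for the permutation mode (local).
#' @return a `stat_result`; `statistic` is the z value (normal mode) or the
#'   squared-rank sum (permutation mode).
#' @export
conover_variance_test <- function(x, y, method = c("normal", "permutation"),
                                  n_perm = 2000, seed = NULL) {
  method <- match.arg(method)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 5 || n2 < 5) stopf("need >= 5 values per group")
  u <- abs(x - mean(x))
  v <- abs(y - mean(y))
  if (all(c(u, v) == 0)) stopf("zero within-group deviation everywhere")
  s2 <- rank(c(u, v))^2
  N <- n1 + n2
  T1 <- sum(s2[seq_len(n1)])
  if (method == "permutation") {
    perm <- with_seed(seed, replicate(n_perm, sum(sample(s2, n1))))
    mu <- n1 * mean(s2)
    p <- (sum(abs(perm - mu) >= abs(T1 - mu)) + 1) / (n_perm + 1)
    return(stat_result("conover_squared_ranks_perm", T1, p, c(n1, n2)))
  }
  s2bar <- mean(s2)
  varT <- n1 * n2 / (N * (N - 1)) * (sum(s2^2) - N * s2bar^2)
  z <- (T1 - n1 * s2bar) / sqrt(varT)
  stat_result("conover_squared_ranks", z, 2 * stats::pnorm(-abs(z)),
              c(n1, n2))
}

#' Exact two-cluster K-means in one dimension
#'
#' The optimal two-cluster partition of scalar values is a split of the
#' sorted sample, so the global optimum is found by scanning all n-1 split
#' points. Inertia is the within-cluster sum of squares; the dispersion
#' explained is `1 - inertia / total sum of squares` about the grand mean.
#'
#' @param values numeric vector (n >= 4).
#' @return list of class `kmeans1d`: `assignment` (1/2 per input value,
#'   cluster 1 = lower), `inertia`, `cluster_means`, `dispersion_explained`,
#'   `split_index` (size of the lower cluster).
#' @export
kmeans_1d_k2 <- function(values) {
  n <- length(values)
  if (n < 4) stopf("need at least 4 values")
  o <- order(values)
  s <- values[o]
  cs <- cumsum(s)
  css <- cumsum(s^2)
  k <- seq_len(n - 1L)
  wss_left <- css[k] - cs[k]^2 / k
  wss_right <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / (n - k)
  wss <- pmax(wss_left + wss_right, 0)
  kbest <- which.min(wss)
  assignment <- integer(n)
  assignment[o] <- rep(c(1L, 2L), c(kbest, n - kbest))
  tss <- css[n] - cs[n]^2 / n
  structure(list(assignment = assignment, inertia = wss[kbest],
                 cluster_means = c(cs[kbest] / kbest,
                                   (cs[n] - cs[kbest]) / (n - kbest)),
                 dispersion_explained = if (tss > 0) 1 - wss[kbest] / tss else 1,
                 split_index = kbest),
            class = "kmeans1d")
}

# vectorised two-cluster inertias for many bootstrap resamples:
# draws is an n_draws x n_reps matrix; returns one inertia per column.
# Columns are sorted with a bubble sorting network (n_draws is small), so
# every step is a vectorised pmin/pmax across all replicates at once.
boot_inertias <- function(draws) {
  n <- nrow(draws)
  S <- draws
  for (i in seq_len(n - 1L)) {
    for (j in seq_len(n - i)) {
      a <- S[j, ]; b <- S[j + 1L, ]
      S[j, ] <- pmin(a, b)
      S[j + 1L, ] <- pmax(a, b)
    }
  }
  cs <- S; css <- S^2
  for (i in 2:n) {
    cs[i, ] <- cs[i - 1L, ] + cs[i, ]
    css[i, ] <- css[i - 1L, ] + css[i, ]
  }
  best <- rep(Inf, ncol(draws))
  for (k in seq_len(n - 1L)) {
    wss <- (css[k, ] - cs[k, ]^2 / k) +
      (css[n, ] - css[k, ]) - (cs[n, ] - cs[k, ])^2 / (n - k)
    best <- pmin(best, wss)
  }
  pmax(best, 0)
}

#' Bootstrap inertia test of bimodality
#'
#' Tests whether an observed sample is more bimodal (has a smaller
#' two-cluster K-means inertia) than expected from resampling a reference
#' distribution: each replicate draws `n_draws` values with replacement
#' from `reference` and records its two-cluster inertia; the one-sided
#' p-value is the (add-one corrected) fraction of bootstrap inertias at or
#' below the observed one.
#'
#' @param reference numeric reference sample (e.g. the failure-rate
#'   distribution of the majority phenotype).
#' @param observed numeric observed sample whose bimodality is tested.
#' @param n_draws values drawn per replicate; defaults to
#'   `length(observed)`.
#' @param n_reps bootstrap replicates (default 10000).
#' @param seed optional integer seed (local).
#' @return list of class `bimodality_result`: `observed_inertia`,
#'   `cluster_means`, `dispersion_explained`, `bootstrap_inertias`,
#'   `p_one_sided`, `n_draws_per_rep`, `n_reps`, `seed`.
#' @export
bootstrap_bimodality <- function(reference, observed, n_draws = NULL,
                                 n_reps = 10000, seed = NULL) {
  n_draws <- n_draws %||% length(observed)
  if (n_draws < 4) stopf("n_draws must be >= 4")
  if (n_reps < 1) stopf("n_reps must be >= 1")
  km <- kmeans_1d_k2(observed)
  if (length(unique(reference)) == 1L) {
    warnf("degenerate reference (all values equal); p = 1")
    return(structure(list(observed_inertia = km$inertia,
                          cluster_means = km$cluster_means,
                          dispersion_explained = km$dispersion_explained,
                          bootstrap_inertias = rep(0, n_reps),
                          p_one_sided = 1, n_draws_per_rep = n_draws,
                          n_reps = n_reps, seed = seed),
                     class = "bimodality_result"))
  }
  boots <- with_seed(seed, {
    draws <- matrix(sample(reference, n_draws * n_reps, replace = TRUE),
                    n_draws, n_reps)
    boot_inertias(draws)
  })
  p <- (sum(boots <= km$inertia) + 1) / (n_reps + 1)
  structure(list(observed_inertia = km$inertia,
                 cluster_means = km$cluster_means,
                 dispersion_explained = km$dispersion_explained,
                 bootstrap_inertias = boots, p_one_sided = p,
                 n_draws_per_rep = n_draws, n_reps = n_reps, seed = seed),
            class = "bimodality_result")
}

#' @export
print.bimodality_result <- function(x, ...) {
  cat(sprintf(paste0("<bimodality> inertia = %.4g, dispersion explained = ",
                     "%.1f%%, one-sided p = %.4g (%d draws x %d reps)\n"),
              x$observed_inertia, 100 * x$dispersion_explained,
              x$p_one_sided, x$n_draws_per_rep, x$n_reps))
  invisible(x)
}

#' Spearman rank correlation with t-distributed p-value
#'
#' Spearman's rho with a two-sided p-value from the t transform on n-2
#' degrees of freedom. When the correlation is significant at 0.05 the
#' linear-regression slope of y on x is reported alongside.
#'
#' @param x,y numeric vectors (n >= 5).
#' @return a `stat_result` with `statistic` = rho, plus `slope` (NA unless
#'   p < 0.05).
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (n < 5 || length(y) != n) stopf("need two vectors of equal length >= 5")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(stat_result("spearman", NA_real_, NA_real_, n,
                       note = "constant input: rho undefined"))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  slope <- if (is.finite(p) && p < 0.05)
    unname(stats::coef(stats::lm(y ~ x))[2L]) else NA_real_
  stat_result("spearman", rho, p, n, slope = slope)
}
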