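# Internal helpers shared across modules. Time base: 0 ms at sweep start,
# stimulus at `stim_time`; all windows half-open [start, end) in ms and
# rounded to the nearest sample on the native grid.

# 1-based sample index of a time in ms (nearest sample)
ms_to_index <- function(ms, sampling_rate) {
  as.integer(round(ms * sampling_rate / 1000)) + 1L
}

index_to_ms <- function(idx, sampling_rate) {
  (idx - 1) * 1000 / sampling_rate
}

# trapezoid integral of y sampled at spacing dx (units: y-units * dx-units)
trapz <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * (sum(y) - (y[1L] + y[n]) / 2)
}

# centred boxcar smoother, width in samples (odd); edges padded by replication
boxcar <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[
    (half + 1L):(half + length(x))]
}

# evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# global RNG stream is left untouched. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
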