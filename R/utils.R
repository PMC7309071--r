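# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package code never perturbs the
# user's random stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and stream indices, kept within
# the 32-bit integer range.
child_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + i) %% 2147483647
  as.integer(s)
}

# Zero-phase Butterworth low-pass with odd-reflection end padding (the
# padding is what keeps very low cutoffs, e.g. 0.3 Hz at 100 Hz, free of
# end transients).
zerophase_lowpass <- function(x, rate, cutoff, order = 4) {
  n <- length(x)
  wn <- cutoff / (rate / 2)
  if (wn <= 0 || wn >= 1) stop("cutoff must lie in (0, rate/2)")
  bf <- signal::butter(order, wn)
  padlen <- min(n - 1L, ceiling(3 * rate / cutoff))
  if (padlen < 3L) stop("series too short for filter warm-up")
  # remove the mean first: the zero-state filter transient is driven by
  # the oscillatory content only, and a constant input is reproduced
  # exactly
  mu <- mean(x)
  xc <- x - mu
  pre  <- 2 * xc[1] - rev(xc[2:(padlen + 1L)])
  post <- 2 * xc[n] - rev(xc[(n - padlen):(n - 1L)])
  y <- signal::filtfilt(bf, c(pre, xc, post))
  y[(padlen + 1L):(padlen + n)] + mu
}

# High-pass companion (used for the band-limited roughness component of the
# synthetic generator): complement of the low-pass.
zerophase_highpass <- function(x, rate, cutoff, order = 4) {
  x - zerophase_lowpass(x, rate, cutoff, order)
}

# Trapezoidal integral and cumulative integral on a uniform grid.
trapz <- function(t, y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}
cumtrapz <- function(t, y) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# Derivative by central differences, one-sided at the endpoints.
central_diff <- function(x, rate) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d
}

# Indices of strict local maxima / minima of a series.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}
local_minima <- function(x) local_maxima(-x)

# Parabolic sub-sample refinement of an extremum at index i.
refine_parabolic <- function(t, x, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(t[i])
  denom <- x[i - 1] - 2 * x[i] + x[i + 1]
  if (abs(denom) < 1e-12) return(t[i])
  delta <- 0.5 * (x[i - 1] - x[i + 1]) / denom
  delta <- max(-0.5, min(0.5, delta))
  t[i] + delta * (t[i] - t[i - 1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
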