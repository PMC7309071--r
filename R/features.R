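# Per-repetition feature registry: time-domain statistics, triad
# statistics, spectral features, and movement-smoothness measures
# (dimensionless jerk, sample entropy, spectral arc length) computed from
# each sensor's aligned signals.

#' Gravity/body decomposition of a tri-axial acceleration
#'
#' The gravity component is the zero-phase low-pass of the acceleration
#' (default 4th-order Butterworth, 0.3 Hz cutoff); the body component is
#' the complement, so `gravity + body == accel` exactly.
#'
#' @param accel3 n x 3 acceleration matrix (g).
#' @param rate sampling rate (Hz).
#' @param cutoff low-pass cutoff (Hz).
#' @param order Butterworth order.
#' @return list with `gravity` and `body` (n x 3 matrices).
#' @export
decompose_gravity_body <- function(accel3, rate, cutoff = 0.3, order = 4) {
  accel3 <- as.matrix(accel3)
  if (nrow(accel3) < 3 * (2 * order + 1))
    stop("series shorter than filter warm-up")
  gravity <- apply(accel3, 2, zerophase_lowpass, rate = rate,
                   cutoff = cutoff, order = order)
  list(gravity = gravity, body = accel3 - gravity)
}

#' Time-domain statistics of a series
#'
#' Mean, standard deviation, skewness, excess kurtosis (both
#' moment-based), RMS, minimum, maximum, peak-to-peak, coefficient of
#' variation (sd/|mean|, undefined when |mean| < 1e-12) and interquartile
#' range.  Undefined values are returned as `NA` (explicit flags, never
#' silent `NaN`).
#'
#' @param x numeric series (non-empty; skewness/kurtosis need >= 4
#'   samples and are `NA` below that).
#' @return named numeric vector of the 10 statistics.
#' @export
time_stats <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty series")
  mu <- mean(x)
  s <- if (n > 1L) sd(x) else 0
  m2 <- mean((x - mu)^2)
  skew <- kurt <- NA_real_
  if (n >= 4L && m2 > 1e-300) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else if (n >= 4L && m2 <= 1e-300) {
    skew <- kurt <- NA_real_
  }
  cv <- if (abs(mu) < 1e-12) NA_real_ else s / abs(mu)
  c(mean = mu, sd = s, skewness = skew, kurtosis = kurt,
    rms = sqrt(mean(x^2)), min = min(x), max = max(x),
    p2p = max(x) - min(x), cv = cv,
    iqr = unname(diff(quantile(x, c(0.25, 0.75), names = FALSE))))
}

#' Triad statistics of a 3-axis signal
#'
#' Pairwise Pearson correlations, per-axis signal energy (mean squared
#' sample) and signal magnitude area (mean of |x|+|y|+|z|).  Correlations
#' involving a zero-variance axis are `NA`.
#'
#' @param signal3 n x 3 matrix.
#' @return named numeric vector of 7 values.
#' @export
triad_stats <- function(signal3) {
  signal3 <- as.matrix(signal3)
  if (ncol(signal3) != 3L) stop("signal3 must have 3 columns")
  sds <- apply(signal3, 2, sd)
  pair_cor <- function(i, j) {
    if (sds[i] < 1e-300 || sds[j] < 1e-300) return(NA_real_)
    cor(signal3[, i], signal3[, j])
  }
  c(corr_xy = pair_cor(1, 2), corr_xz = pair_cor(1, 3),
    corr_yz = pair_cor(2, 3),
    energy_x = mean(signal3[, 1]^2), energy_y = mean(signal3[, 2]^2),
    energy_z = mean(signal3[, 3]^2),
    sma = mean(abs(signal3[, 1]) + abs(signal3[, 2]) + abs(signal3[, 3])))
}

# One-sided power spectrum of the detrended, Hann-windowed series.
power_spectrum <- function(x, rate) {
  n <- length(x)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), x)
  xd <- fit$residuals
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  X <- fft(xd * w)
  k <- 0:(n %/% 2)
  list(f = k * rate / n, p = Mod(X[k + 1L])^2)
}

#' Spectral features of a series
#'
#' Dominant frequency, spectral centroid, spectral edge frequency (the
#' frequency below which `sef_quantile` of the power lies), harmonic
#' ratio (even- over odd-harmonic power at multiples of the dominant
#' frequency) and index of harmonicity (dominant power over the first
#' `n_harmonics_ioh` harmonics), all on the one-sided periodogram of the
#' detrended, Hann-windowed series.  Harmonic powers are read at the bin
#' nearest each harmonic.
#'
#' @param x numeric series, length >= 64.
#' @param rate sampling rate (Hz).
#' @param sef_quantile spectral edge power fraction.
#' @param n_harmonics_hr harmonics for the harmonic ratio (even/odd split).
#' @param n_harmonics_ioh harmonics for the index of harmonicity.
#' @return named numeric vector: `dominant_freq`, `spectral_centroid`,
#'   `spectral_edge`, `harmonic_ratio`, `index_harmonicity` (`NA` when
#'   undefined, e.g. an all-zero series).
#' @export
spectral_features <- function(x, rate, sef_quantile = 0.95,
                              n_harmonics_hr = 10, n_harmonics_ioh = 6) {
  if (length(x) < 64L) stop("series must have at least 64 samples")
  na_out <- c(dominant_freq = NA_real_, spectral_centroid = NA_real_,
              spectral_edge = NA_real_, harmonic_ratio = NA_real_,
              index_harmonicity = NA_real_)
  if (all(abs(x - x[1]) < 1e-300)) return(na_out)
  sp <- power_spectrum(x, rate)
  f <- sp$f[-1]; p <- sp$p[-1]
  tot <- sum(p)
  if (tot <= 1e-300) return(na_out)
  i_dom <- which.max(p)
  f_dom <- f[i_dom]
  centroid <- sum(f * p) / tot
  sef <- f[which(cumsum(p) >= sef_quantile * tot)[1]]
  harm_power <- function(h) {
    fh <- h * f_dom
    if (fh > rate / 2) return(0)
    p[which.min(abs(f - fh))]
  }
  hp <- vapply(seq_len(n_harmonics_hr), harm_power, numeric(1))
  odd <- sum(hp[seq(1, n_harmonics_hr, by = 2)])
  hr <- if (odd <= 1e-300) NA_real_
        else sum(hp[seq(2, n_harmonics_hr, by = 2)]) / odd
  denom <- sum(vapply(seq_len(n_harmonics_ioh), harm_power, numeric(1)))
  ioh <- if (denom <= 1e-300) NA_real_ else p[i_dom] / denom
  c(dominant_freq = f_dom, spectral_centroid = centroid,
    spectral_edge = sef, harmonic_ratio = hr, index_harmonicity = ioh)
}

#' Dimensionless jerk smoothness of an acceleration profile
#'
#' Treats the axis as an acceleration record of a movement: the speed
#' proxy is the cumulative trapezoidal integral of the mean-removed
#' acceleration, jerk is its derivative, and the measure is
#' `-(T^3 / v_peak^2) * integral(jerk^2)` (dimensionless; invariant to
#' amplitude scaling).  The negative-log variant `-ln(...)` is returned
#' by default; larger values mean smoother movement.
#'
#' @param accel_axis acceleration series (g), length >= 3.
#' @param rate sampling rate (Hz).
#' @param log return the negative-log variant (default) instead of the
#'   negated raw measure.
#' @return scalar; `NA` when the peak of the speed proxy is zero.
#' @export
dimensionless_jerk <- function(accel_axis, rate, log = TRUE) {
  n <- length(accel_axis)
  if (n < 3L) stop("need at least 3 samples")
  t <- seq(0, n - 1) / rate
  v <- cumtrapz(t, accel_axis - mean(accel_axis))
  v_peak <- max(abs(v))
  if (v_peak < 1e-300) return(NA_real_)
  j <- central_diff(accel_axis, rate)
  dur <- t[n]
  dlj <- dur^3 / v_peak^2 * trapz(t, j^2)
  if (log) -base::log(dlj) else -dlj
}

#' Sample entropy of a series
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `r` and `A` counts those whose length-(m+1)
#' extensions also match; self-matches are excluded.  Lower values mean a
#' more regular signal.
#'
#' @param x numeric series, length >= m + 2.
#' @param m template length (default 2).
#' @param r tolerance; defaults to `0.2 * sd(x)`.
#' @return scalar with attribute `counts = c(A, B)`; `NA` when no
#'   template pair matches (`B = 0`) or no extension matches (`A = 0`).
#'   A constant series returns 0.
#' @export
sample_entropy <- function(x, m = 2L, r = NULL) {
  n <- length(x)
  if (n < m + 2L) stop("series must have length >= m + 2")
  s <- sd(x)
  if (is.null(r)) {
    if (s < 1e-300) return(structure(0, counts = c(A = NA, B = NA)))
    r <- 0.2 * s
  }
  if (r <= 0) stop("r must be positive")
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  out <- if (cnt["B"] == 0 || cnt["A"] == 0) NA_real_
         else -base::log(cnt["A"] / cnt["B"])
  structure(unname(out), counts = cnt)
}

#' Spectral arc length (SPARC) smoothness
#'
#' Negative arc length of the max-normalized magnitude spectrum over
#' `[0, fc]`, with the adaptive amplitude cutoff of the canonical SPARC
#' definition (zero-padding level 4, `fc` 10 Hz, amplitude threshold
#' 0.05).  More negative values mean a less smooth movement; the value is
#' invariant to amplitude scaling.
#'
#' @param x numeric series, length >= 64.
#' @param rate sampling rate (Hz).
#' @param fc spectral cutoff (Hz).
#' @param amp_th adaptive amplitude threshold on the normalized spectrum.
#' @param padlevel zero-padding exponent added to `ceil(log2(n))`.
#' @return scalar; `NA` for an all-zero series.
#' @export
sparc <- function(x, rate, fc = 10, amp_th = 0.05, padlevel = 4) {
  n <- length(x)
  if (n < 64L) stop("series must have at least 64 samples")
  nfft <- 2^(ceiling(log2(n)) + padlevel)
  f <- (0:(nfft - 1)) * rate / nfft
  Mf <- Mod(fft(c(x, numeric(nfft - n))))
  mmax <- max(Mf)
  if (mmax < 1e-300) return(NA_real_)
  Mf <- Mf / mmax
  sel <- which(f <= fc)
  f_sel <- f[sel]; m_sel <- Mf[sel]
  above <- which(m_sel >= amp_th)
  if (length(above) < 2L) return(NA_real_)
  keep <- above[1]:above[length(above)]
  f_sel <- f_sel[keep]; m_sel <- m_sel[keep]
  frange <- f_sel[length(f_sel)] - f_sel[1]
  if (frange <= 0) return(NA_real_)
  -sum(sqrt((diff(f_sel) / frange)^2 + diff(m_sel)^2))
}

#' Derived signal set of one sensor
#'
#' The signals feature extraction draws on: the tri-axial angular rate,
#' tri-axial acceleration and its magnitude, the jerk (time-derivative of
#' acceleration, central differences), and the gravity/body decomposition
#' of the acceleration.
#'
#' @param rec uniformly sampled `imu_recording`.
#' @param gravity_cutoff low-pass cutoff (Hz) of the gravity estimate.
#' @return list with `gyro3`, `accel3`, `accel_mag`, `jerk3`, `body3`,
#'   `gravity3`, `rate`.
#' @export
signal_set <- function(rec, gravity_cutoff = 0.3) {
  rate <- rec$nominal_rate
  dec <- decompose_gravity_body(rec$accel, rate, cutoff = gravity_cutoff)
  list(gyro3 = rec$gyro, accel3 = rec$accel,
       accel_mag = sqrt(rowSums(rec$accel^2)),
       jerk3 = apply(rec$accel, 2, central_diff, rate = rate),
       body3 = dec$body, gravity3 = dec$gravity, rate = rate)
}

#' Feature registry configuration
#'
#' Defines which sensors contribute and the parameters of each feature
#' family.  Per sensor the registry holds 223 named scalars: 10 time
#' statistics on 13 signals (gyro/jerk/body/gravity axes and the
#' acceleration magnitude), 7 triad statistics on 4 tri-axial signals,
#' 5 spectral features on 10 series (gyro, raw acceleration and jerk axes
#' plus the acceleration magnitude), dimensionless jerk per acceleration
#' axis, and sample entropy and SPARC per gyro and acceleration axis.
#'
#' @param sensors sensor ids included (default all four; a single-sensor
#'   registry is a supported configuration).
#' @param gravity_cutoff gravity low-pass cutoff (Hz).
#' @param sampen_m,sampen_r_frac sample-entropy template length and
#'   tolerance as a fraction of the series SD.
#' @param sparc_fc SPARC spectral cutoff (Hz).
#' @return object of class `feature_registry`.
#' @export
feature_registry <- function(sensors = SENSOR_IDS, gravity_cutoff = 0.3,
                             sampen_m = 2L, sampen_r_frac = 0.2,
                             sparc_fc = 10) {
  structure(list(sensors = sensors, gravity_cutoff = gravity_cutoff,
                 sampen_m = as.integer(sampen_m),
                 sampen_r_frac = sampen_r_frac, sparc_fc = sparc_fc),
            class = "feature_registry")
}

#' Number of features a registry defines
#' @param registry a [feature_registry()].
#' @return integer count (223 per sensor).
#' @export
registry_size <- function(registry) {
  223L * length(registry$sensors)
}

# Feature vector of one sensor's signal set.
sensor_features <- function(ss, registry) {
  axes <- c("x", "y", "z")
  out <- numeric(0)
  add <- function(out, vals, prefix) {
    names(vals) <- paste(prefix, names(vals), sep = ".")
    c(out, vals)
  }
  ts_signals <- list()
  for (a in 1:3) ts_signals[[paste0("gyro_", axes[a])]] <- ss$gyro3[, a]
  for (a in 1:3) ts_signals[[paste0("jerk_", axes[a])]] <- ss$jerk3[, a]
  for (a in 1:3) ts_signals[[paste0("body_", axes[a])]] <- ss$body3[, a]
  for (a in 1:3) ts_signals[[paste0("gravity_", axes[a])]] <- ss$gravity3[, a]
  ts_signals$accel_mag <- ss$accel_mag
  for (nm in names(ts_signals))
    out <- add(out, time_stats(ts_signals[[nm]]), nm)
  triads <- list(gyro = ss$gyro3, jerk = ss$jerk3, body = ss$body3,
                 gravity = ss$gravity3)
  for (nm in names(triads)) out <- add(out, triad_stats(triads[[nm]]), nm)
  sp_signals <- list()
  for (a in 1:3) sp_signals[[paste0("gyro_", axes[a])]] <- ss$gyro3[, a]
  for (a in 1:3) sp_signals[[paste0("accel_", axes[a])]] <- ss$accel3[, a]
  for (a in 1:3) sp_signals[[paste0("jerk_", axes[a])]] <- ss$jerk3[, a]
  sp_signals$accel_mag <- ss$accel_mag
  for (nm in names(sp_signals)) {
    v <- tryCatch(spectral_features(sp_signals[[nm]], ss$rate),
                  error = function(e) rep(NA_real_, 5))
    if (is.null(names(v)))
      names(v) <- c("dominant_freq", "spectral_centroid", "spectral_edge",
                    "harmonic_ratio", "index_harmonicity")
    out <- add(out, v, nm)
  }
  for (a in 1:3)
    out <- add(out, c(dimensionless_jerk =
                        dimensionless_jerk(ss$accel3[, a], ss$rate)),
               paste0("accel_", axes[a]))
  se_signals <- c(paste0("gyro_", axes), paste0("accel_", axes))
  se_data <- c(lapply(1:3, function(a) ss$gyro3[, a]),
               lapply(1:3, function(a) ss$accel3[, a]))
  names(se_data) <- se_signals
  for (nm in se_signals) {
    x <- se_data[[nm]]
    se <- as.numeric(sample_entropy(x, m = registry$sampen_m,
                                    r = registry$sampen_r_frac * sd(x) + 1e-12))
    out <- add(out, c(sample_entropy = se), nm)
    out <- add(out, c(sparc = sparc(x, ss$rate, fc = registry$sparc_fc)), nm)
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Extract the feature vector of a repetition
#'
#' Applies the registry to each configured sensor of an aligned
#' repetition and concatenates the per-sensor vectors with
#' sensor-prefixed names.  The name ordering is fixed and identical
#' across repetitions; undefined features are explicit `NA`s, never
#' silent `NaN`s.
#'
#' @param arep an `aligned_repetition`.
#' @param registry a [feature_registry()].
#' @return named numeric vector of length [registry_size()], with
#'   attributes `subject`, `cohort`, `direction`, `trial`.
#' @export
extract_features <- function(arep, registry = feature_registry()) {
  out <- numeric(0)
  for (sid in registry$sensors) {
    rec <- arep$signals[[sid]]
    if (is.null(rec)) stop(sprintf("sensor %s missing from repetition", sid))
    ss <- signal_set(rec, gravity_cutoff = registry$gravity_cutoff)
    v <- sensor_features(ss, registry)
    names(v) <- paste(sid, names(v), sep = ".")
    out <- c(out, v)
  }
  structure(out, subject = arep$subject, cohort = arep$cohort,
            direction = arep$direction, trial = arep$trial)
}

#' Feature matrix of a whole dataset
#'
#' Runs preprocessing and feature extraction over every repetition of a
#' synthetic dataset and assembles the feature matrix with metadata
#' columns.
#'
#' @param cohorts an `imu_cohorts` object (with waveforms).
#' @param registry a [feature_registry()].
#' @param target_rate resampling rate (Hz) for preprocessing.
#' @return data.frame: `subject`, `cohort`, `direction`, `trial`, then
#'   one column per registry feature.
#' @export
feature_matrix <- function(cohorts, registry = feature_registry(),
                           target_rate = 100) {
  rows <- lapply(cohorts$repetitions, function(rep) {
    arep <- preprocess_repetition(rep, target_rate = target_rate)
    extract_features(arep, registry)
  })
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    subject = vapply(cohorts$repetitions, function(r) r$subject, character(1)),
    cohort = vapply(cohorts$repetitions, function(r) r$cohort, character(1)),
    direction = vapply(cohorts$repetitions, function(r) r$direction,
                       character(1)),
    trial = vapply(cohorts$repetitions, function(r) r$trial, integer(1)),
    stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(feats, check.names = FALSE))
  rownames(out) <- NULL
  out
}
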