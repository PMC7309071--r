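test_that("gravity/body decomposition is complementary and accurate", {
  # constant acceleration: gravity is the constant, body is zero
  a <- matrix(rep(c(0, 0, 1), each = 400), ncol = 3)
  dec <- decompose_gravity_body(a, 100)
  expect_lt(max(abs(dec$gravity - a)), 1e-6)
  expect_lt(max(abs(dec$body)), 1e-6)
  # 5 Hz sine on y over a 1 g vertical baseline
  t <- seq(0, 10, by = 0.01)
  a2 <- cbind(0, sin(2 * pi * 5 * t), 1)
  dec2 <- decompose_gravity_body(a2, 100)
  expect_lt(max(abs(dec2$gravity[, 3] - 1)), 0.02)
  expect_lt(max(abs(dec2$body[, 2] - a2[, 2])), 0.02)
  # complementarity on arbitrary input
  set.seed(3)
  a3 <- matrix(rnorm(900), ncol = 3)
  dec3 <- decompose_gravity_body(a3, 100)
  expect_lt(max(abs(dec3$gravity + dec3$body - a3)), 1e-9)
  expect_error(decompose_gravity_body(a3[1:10, ], 100), "warm-up")
})

test_that("time statistics match their definitions", {
  s <- time_stats(c(1, 1, 1, 1))
  expect_equal(s[["mean"]], 1)
  expect_equal(s[["sd"]], 0)
  expect_equal(s[["p2p"]], 0)
  expect_equal(s[["rms"]], 1)
  expect_true(is.na(s[["skewness"]]))   # zero-variance: flagged

  x <- c(-2, -1, 1, 2)
  s2 <- time_stats(x)
  expect_equal(s2[["mean"]], 0)
  expect_equal(s2[["rms"]], sqrt(mean(x^2)))
  expect_equal(s2[["rms"]], 1.5811, tolerance = 1e-4)
  expect_equal(s2[["p2p"]], 4)
  expect_equal(s2[["iqr"]],
               quantile(x, 0.75, names = FALSE) -
                 quantile(x, 0.25, names = FALSE))
  expect_true(is.na(s2[["cv"]]))        # |mean| < 1e-12: flagged

  set.seed(7)
  z <- rnorm(1e5)
  s3 <- time_stats(z)
  expect_lt(abs(s3[["skewness"]]), 0.05)
  expect_lt(abs(s3[["kurtosis"]]), 0.05)
  expect_error(time_stats(numeric(0)), "empty")
})

test_that("triad statistics equal brute-force formulas", {
  x <- cbind(c(1, -1, 1, -1), c(1, -1, 1, -1), c(0.5, 0.5, 0.5, 0.5))
  s <- triad_stats(x)
  expect_equal(s[["corr_xy"]], 1)
  expect_true(is.na(s[["corr_xz"]]))    # zero-variance z axis
  expect_equal(s[["energy_x"]], 1)
  expect_equal(s[["sma"]], mean(abs(x[, 1]) + abs(x[, 2]) + abs(x[, 3])))

  set.seed(12)
  y <- matrix(rnorm(300), ncol = 3)
  s2 <- triad_stats(y)
  oracle_cor <- function(a, b) {
    ma <- sum(a) / length(a); mb <- sum(b) / length(b)
    sum((a - ma) * (b - mb)) /
      sqrt(sum((a - ma)^2) * sum((b - mb)^2))
  }
  expect_equal(s2[["corr_xy"]], oracle_cor(y[, 1], y[, 2]), tolerance = 1e-12)
  expect_equal(s2[["corr_yz"]], oracle_cor(y[, 2], y[, 3]), tolerance = 1e-12)
  expect_equal(s2[["energy_y"]], sum(y[, 2]^2) / nrow(y), tolerance = 1e-12)
})

test_that("spectral features identify a pure and a two-tone spectrum", {
  t <- seq(0, 10 - 0.01, by = 0.01)
  x <- sin(2 * pi * 2 * t)
  sp <- spectral_features(x, 100)
  expect_lt(abs(sp[["dominant_freq"]] - 2), 0.1)
  expect_lt(abs(sp[["spectral_centroid"]] - 2), 0.1)
  expect_gt(sp[["index_harmonicity"]], 0.95)

  # harmonic ratio against an independent O(n^2) DFT oracle
  x2 <- sin(2 * pi * 2 * t) + sin(2 * pi * 4 * t)
  sp2 <- spectral_features(x2, 100)
  n <- length(x2)
  tt <- seq_len(n)
  fitc <- stats::lm.fit(cbind(1, tt), x2)
  xd <- fitc$residuals * 0.5 * (1 - cos(2 * pi * (tt - 1) / (n - 1)))
  k <- 0:(n %/% 2)
  P <- vapply(k, function(kk) {
    Mod(sum(xd * exp(-2i * pi * kk * (tt - 1) / n)))^2
  }, numeric(1))
  f <- k * 100 / n
  fp <- f[-1]; Pp <- P[-1]
  fd <- fp[which.max(Pp)]
  hp <- vapply(1:10, function(h) {
    if (h * fd > 50) return(0)
    Pp[which.min(abs(fp - h * fd))]
  }, numeric(1))
  hr_oracle <- sum(hp[c(2, 4, 6, 8, 10)]) / sum(hp[c(1, 3, 5, 7, 9)])
  expect_equal(sp2[["harmonic_ratio"]], hr_oracle, tolerance = 1e-9)

  # flat spectrum: spectral edge near 95% of Nyquist
  set.seed(5)
  w <- rnorm(4096)
  spw <- spectral_features(w, 100)
  expect_lt(abs(spw[["spectral_edge"]] - 0.95 * 50) / (0.95 * 50), 0.05)

  expect_true(all(is.na(spectral_features(rep(0, 256), 100))))
  expect_error(spectral_features(rnorm(32), 100), "64")
})

test_that("dimensionless jerk is scale-invariant and matches a closed form", {
  t <- seq(0, 1, by = 0.01)
  a <- 6 * pi * cos(2 * pi * t) # arbitrary smooth profile
  expect_equal(dimensionless_jerk(a, 100), dimensionless_jerk(5 * a, 100),
               tolerance = 1e-12)

  # minimum-jerk movement: acceleration x''(t) of x = 10 t^3 - 15 t^4 + 6 t^5
  tau <- seq(0, 1, by = 1 / 200)
  accel <- 60 * tau - 180 * tau^2 + 120 * tau^3
  # closed-form speed and jerk of the same movement
  v <- 30 * tau^2 - 60 * tau^3 + 30 * tau^4
  jerk <- 60 - 360 * tau + 360 * tau^2
  dlj_oracle <- -(1^3 / max(abs(v))^2) *
    sum((jerk[-1]^2 + jerk[-length(jerk)]^2) / 2 * diff(tau))
  expect_equal(dimensionless_jerk(accel, 200, log = FALSE), dlj_oracle,
               tolerance = 0.01)

  # roughening strictly degrades smoothness
  set.seed(6)
  rough <- accel + 0.15 * sin(2 * pi * 30 * tau)
  expect_lt(dimensionless_jerk(rough, 200), dimensionless_jerk(accel, 200))
  expect_true(is.na(dimensionless_jerk(rep(0, 100), 100)))
})

test_that("sample entropy matches an exhaustive template-count oracle", {
  expect_equal(as.numeric(sample_entropy(rep(3.7, 50))), 0)

  sampen_oracle <- function(x, m, r) {
    n <- length(x)
    A <- 0; B <- 0
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (j <= i) next
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
          B <- B + 1
          if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
        }
      }
    }
    c(A = A, B = B)
  }
  # strictly increasing ramp at tolerance 0.5: no template matches
  cnt <- attr(sample_entropy(1:20, m = 2, r = 0.5), "counts")
  orc <- sampen_oracle(1:20, 2, 0.5)
  expect_equal(unname(cnt), unname(orc))
  expect_equal(unname(orc[["B"]]), 0)
  expect_true(is.na(sample_entropy(1:20, m = 2, r = 0.5)))

  set.seed(8)
  x <- round(rnorm(60), 2)
  got <- sample_entropy(x, m = 2, r = 0.3)
  orc2 <- sampen_oracle(x, 2, 0.3)
  expect_equal(unname(attr(got, "counts")), unname(orc2))
  expect_equal(as.numeric(got), -log(orc2[["A"]] / orc2[["B"]]),
               tolerance = 1e-12)

  # periodic signal is more regular than its shuffled version
  per <- rep(sin(2 * pi * (1:25) / 25), 8)
  set.seed(9)
  shuf <- sample(per)
  expect_lt(as.numeric(sample_entropy(per)), as.numeric(sample_entropy(shuf)))
})

test_that("SPARC is scale-invariant and matches a direct DFT evaluation", {
  t <- seq(0, 2, by = 0.01)
  x <- exp(-((t - 1) / 0.2)^2)
  expect_equal(sparc(x, 100), sparc(10 * x, 100), tolerance = 1e-12)

  # ripple strictly degrades smoothness
  ripple <- x + 0.3 * sin(2 * pi * 8 * t) * (x > 0.05)
  expect_lt(sparc(ripple, 100), sparc(x, 100))

  # single sinusoid against a direct O(n^2) DFT arc-length evaluation
  y <- sin(2 * pi * 3 * t)
  n <- length(y)
  nfft <- 2^(ceiling(log2(n)) + 4)
  k <- 0:(nfft - 1)
  M <- vapply(k, function(kk) {
    Mod(sum(y * exp(-2i * pi * kk * (0:(n - 1)) / nfft)))
  }, numeric(1))
  M <- M / max(M)
  f <- k * 100 / nfft
  sel <- f <= 10
  fs <- f[sel]; Ms <- M[sel]
  above <- which(Ms >= 0.05)
  keep <- above[1]:above[length(above)]
  fs <- fs[keep]; Ms <- Ms[keep]
  oracle <- -sum(sqrt((diff(fs) / (fs[length(fs)] - fs[1]))^2 + diff(Ms)^2))
  expect_equal(sparc(y, 100), oracle, tolerance = 1e-9)

  expect_true(is.na(sparc(rep(0, 128), 100)))
})

test_that("the registry produces a stable, fully named feature vector", {
  spec <- cohort_spec(seed = 23)
  rep <- generate_repetition(spec, "S5", "acl", 1, "left")
  arep <- preprocess_repetition(rep)
  reg <- feature_registry()
  fv <- extract_features(arep, reg)
  expect_length(fv, registry_size(reg))
  expect_length(fv, 892L)
  expect_false(any(duplicated(names(fv))))
  expect_false(any(is.nan(fv)))   # undefined values are NA flags, not NaN
  # determinism: identical repetition gives the identical vector
  fv2 <- extract_features(preprocess_repetition(rep), reg)
  expect_identical(unname(fv), unname(fv2))
  expect_identical(names(fv), names(fv2))
  # single-sensor registry
  reg1 <- feature_registry(sensors = "left_shank")
  fv1 <- extract_features(arep, reg1)
  expect_length(fv1, 223L)
  expect_true(all(startsWith(names(fv1), "left_shank.")))
})

test_that("an all-zero repetition yields zero locations and flagged spectra", {
  t <- seq(0, 8, by = 0.01)
  n <- length(t)
  zero_rec <- function(id)
    imu_recording(id, t, matrix(0, n, 3), matrix(0, n, 3), 100)
  arep <- structure(list(
    signals = list(left_shank = zero_rec("left_shank"),
                   left_thigh = zero_rec("left_thigh"),
                   right_shank = zero_rec("right_shank"),
                   right_thigh = zero_rec("right_thigh")),
    rate = 100, offsets = NULL, rotations = list(),
    subject = "Z", cohort = "healthy", trial = 1L, direction = "left"),
    class = "aligned_repetition")
  fv <- extract_features(arep)
  expect_equal(unname(fv["left_shank.gyro_x.mean"]), 0)
  expect_equal(unname(fv["left_shank.accel_mag.sd"]), 0)
  expect_equal(unname(fv["right_thigh.jerk_z.p2p"]), 0)
  expect_true(is.na(fv["left_shank.gyro_x.dominant_freq"]))
  expect_true(is.na(fv["left_shank.accel_x.sparc"]))
  expect_length(fv, 892L)
})
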