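test_that("resampling a uniform series at the same rate is the identity", {
  t <- seq(0, 2, by = 0.01)
  n <- length(t)
  rec <- imu_recording("left_shank", t, matrix(sin(1:(3 * n)), ncol = 3),
                       matrix(cos(1:(3 * n)), ncol = 3), 100)
  out <- resample_uniform(rec, 100)
  expect_equal(out$t, t, tolerance = 1e-12)
  expect_equal(out$accel, rec$accel, tolerance = 1e-12)
  expect_equal(out$gyro, rec$gyro, tolerance = 1e-12)
})

test_that("resampling recovers a band-limited signal from jittered times", {
  set.seed(4)
  t <- sort(seq(0, 10, by = 0.004) + runif(2501, -0.001, 0.001))
  t <- t[c(TRUE, diff(t) > 1e-6)]
  sine <- function(x) sin(2 * pi * 2 * x)
  rec <- imu_recording("left_shank", t,
                       cbind(sine(t), 0, 1), matrix(0, length(t), 3), 100)
  out <- resample_uniform(rec, 100)
  expect_lt(max(abs(out$accel[, "ax"] - sine(out$t))), 1e-3)
})

test_that("the resampled grid has floor(span * rate) + 1 points", {
  t <- seq(0, 1, by = 0.005)
  rec <- imu_recording("left_shank", t, matrix(1, length(t), 3),
                       matrix(0, length(t), 3), 200)
  expect_length(resample_uniform(rec, 100)$t, 101L)
  expect_length(resample_uniform(rec, 200)$t, 201L)
})

test_that("resampling is idempotent at a fixed rate", {
  set.seed(9)
  t <- sort(runif(400, 0, 4))
  t <- t[c(TRUE, diff(t) > 1e-4)]
  rec <- imu_recording("left_shank", t, matrix(rnorm(3 * length(t)), ncol = 3),
                       matrix(rnorm(3 * length(t)), ncol = 3), 100)
  once <- resample_uniform(rec, 100)
  twice <- resample_uniform(once, 100)
  expect_equal(twice$accel, once$accel, tolerance = 1e-12)
  expect_equal(twice$t, once$t, tolerance = 1e-12)
})

test_that("non-monotone sample times are rejected with the offending index", {
  t <- c(0, 0.01, 0.02, 0.015, 0.03)
  expect_error(
    imu_recording("left_shank", t, matrix(0, 5, 3), matrix(0, 5, 3), 100),
    "index 4")
})

test_that("squat sync recovers known clock offsets", {
  spec <- lownoise_spec(seed = 3, clock_offset_range = 0)
  rep <- generate_repetition(spec, "S1", "healthy", 1, "left")
  recs <- lapply(rep$sensors, resample_uniform, target_rate = 100)
  # identical clocks: all offsets (essentially) zero
  off0 <- detect_squat_sync(recs)
  expect_lt(max(abs(off0)), 0.01)
  # impose the known offsets by shifting time stamps
  known <- c(0, 0.12, -0.3, 0.25)
  shifted <- Map(function(r, d) {
    imu_recording(r$sensor_id, r$t + d, r$accel, r$gyro, r$nominal_rate)
  }, recs, known)
  off <- detect_squat_sync(shifted)
  expect_lt(max(abs(off - (known - known[1]) - off0)), 0.01)
  expect_lt(max(abs(off - known)), 0.011)
})

test_that("squat sync is translation-equivariant", {
  spec <- lownoise_spec(seed = 6, clock_offset_range = 0)
  rep <- generate_repetition(spec, "S1", "healthy", 1, "left")
  recs <- lapply(rep$sensors, resample_uniform, target_rate = 100)
  base <- detect_squat_sync(recs)
  delta <- 0.37
  recs2 <- recs
  recs2[[3]] <- imu_recording(recs[[3]]$sensor_id, recs[[3]]$t + delta,
                              recs[[3]]$accel, recs[[3]]$gyro, 100)
  shifted <- detect_squat_sync(recs2)
  expect_equal(shifted[3] - base[3], c(right_shank = delta),
               tolerance = 1e-6)
})

test_that("squat sync recovers generator clock offsets within a sample", {
  spec <- lownoise_spec(seed = 9)   # offsets drawn in +/- 0.5 s, no rate error
  rep <- generate_repetition(spec, "S1", "healthy", 1, "left")
  recs <- lapply(rep$sensors, resample_uniform, target_rate = 100)
  off <- detect_squat_sync(recs)
  tru <- rep$truth$clock_offsets - rep$truth$clock_offsets[1]
  expect_lt(max(abs(off - tru)), 0.01)
})

test_that("a stream without a squat raises a sync failure", {
  expect_error(detect_squat_sync(list(flat_recording())), "sync failure")
})

test_that("a known 20-degree shank yaw is recovered within 1 degree", {
  spec <- lownoise_spec(seed = 5, clock_offset_range = 0,
                        shank_yaw_range = 0)
  rep <- generate_repetition(spec, "S1", "healthy", 1, "left")
  sh <- resample_uniform(rep$sensors$left_shank, 100)
  th <- resample_uniform(rep$sensors$left_thigh, 100)
  R20 <- matrix(c(cos(pi / 9), sin(pi / 9), 0,
                  -sin(pi / 9), cos(pi / 9), 0, 0, 0, 1), 3, 3)
  rotated <- imu_recording("left_shank", sh$t, sh$accel %*% t(R20),
                           sh$gyro %*% t(R20), 100)
  al <- align_shank_frame(rotated, th)
  yaw <- atan2(al$rotation[1, 2], al$rotation[1, 1]) * 180 / pi
  expect_lt(abs(yaw - 20), 1)
  # already-aligned data: rotation within 1 degree of the identity
  al0 <- align_shank_frame(sh, th)
  yaw0 <- atan2(al0$rotation[1, 2], al0$rotation[1, 1]) * 180 / pi
  expect_lt(abs(yaw0), 1)
})

test_that("shank rotation is orthonormal and preserves sample norms", {
  spec <- cohort_spec(seed = 21)
  rep <- generate_repetition(spec, "S1", "acl", 2, "right")
  arep <- preprocess_repetition(rep)
  for (leg in c("left", "right")) {
    R <- arep$rotations[[paste0(leg, "_shank")]]
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
  }
  sh <- resample_uniform(rep$sensors$left_shank, 100)
  al <- align_shank_frame(sh, resample_uniform(rep$sensors$left_thigh, 100))
  expect_lt(max(abs(sqrt(rowSums(al$recording$gyro^2)) -
                    sqrt(rowSums(sh$gyro^2)))), 1e-9)
})

test_that("pure-noise input yields a flagged or failed hinge axis", {
  t <- seq(0, 8, by = 0.01)
  n <- length(t)
  set.seed(2)
  ns <- imu_recording("left_shank", t, matrix(rnorm(3 * n, 0, 0.05), ncol = 3),
                      matrix(rnorm(3 * n, 0, 5), ncol = 3), 100)
  nt <- imu_recording("left_thigh", t, matrix(rnorm(3 * n, 0, 0.05), ncol = 3),
                      matrix(rnorm(3 * n, 0, 5), ncol = 3), 100)
  expect_error(align_shank_frame(ns, nt), "low-confidence|converge")
  res <- align_shank_frame(ns, nt, strict = FALSE)
  expect_true(res$low_confidence)
})

test_that("preprocessing yields a shared uniform grid across sensors", {
  spec <- cohort_spec(seed = 17)
  rep <- generate_repetition(spec, "S9", "healthy", 1, "right")
  arep <- preprocess_repetition(rep)
  ts <- lapply(arep$signals, `[[`, "t")
  for (k in 2:4) expect_identical(ts[[k]], ts[[1]])
  expect_equal(unique(round(diff(ts[[1]]), 12)), 0.01)
})
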