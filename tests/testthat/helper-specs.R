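# Generator configurations used across the suite.

# Perfect clocks, no noise: ground truth is exactly recoverable.
clean_spec <- function(seed = 2, ...) {
  args <- list(seed = seed, clock_offset_range = 0, rate_error = 0,
               time_jitter = 0, noise_sd_accel = 0, noise_sd_gyro = 0,
               hf_accel_sd = 0, shank_yaw_range = 0,
               gct_sd_within = 0, gct_sd_between = 0,
               stance_fraction_sd = 0)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_spec, args)
}

# Light sensor noise, ideal clocks unless overridden: used where sub-sample
# recovery is asserted in the presence of some measurement noise.
lownoise_spec <- function(seed = 2, ...) {
  args <- list(seed = seed, rate_error = 0, time_jitter = 0,
               noise_sd_accel = 0.01, noise_sd_gyro = 1, hf_accel_sd = 0.02)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(cohort_spec, args)
}

# A flat 1 g recording with no squat (negative control for sync).
flat_recording <- function(sensor_id = "left_shank", duration = 8,
                           rate = 100, seed = 1) {
  t <- seq(0, duration, by = 1 / rate)
  n <- length(t)
  set.seed(seed)
  imu_recording(sensor_id, t,
                cbind(rnorm(n, 0, 0.01), rnorm(n, 0, 0.01),
                      1 + rnorm(n, 0, 0.01)),
                matrix(rnorm(3 * n, 0, 1), ncol = 3), rate)
}
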