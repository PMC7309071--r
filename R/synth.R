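# Synthetic multi-sensor IMU data for a run-and-sidestep task.
#
# Each repetition emulates the study protocol: a deep squat used for
# temporal synchronization, a ~5 m run to a side-step, a 45-degree sidestep
# (left or right), and a short run to a stop.  Four sensors (left/right
# shank and thigh) record tri-axial acceleration (g) and angular rate
# (deg/s) at a nominal 100 Hz, with per-sensor clock offsets, rate errors
# and timestamp jitter so that resampling and synchronization are
# exercised downstream.  Ground-truth gait events and clock parameters are
# returned alongside every repetition for oracle testing.

SENSOR_IDS <- c("left_shank", "left_thigh", "right_shank", "right_thigh")

#' Cohort specification for the synthetic IMU generator
#'
#' Bundles every tunable of the two-cohort generator: cohort sizes, the
#' per-group/limb mean gait cycle times the stride trains are drawn around,
#' stance fraction, the affected-limb roughness multiplier applied to
#' high-frequency (>6 Hz) acceleration content, sensor noise levels, and
#' the clock model (per-sensor offset, rate error, timestamp jitter).
#'
#' Default gait cycle time means are the study-scale values for a
#' run-and-sidestep task: healthy left 0.49 s, healthy right 0.509 s,
#' post-ACL affected (left) 0.514 s, post-ACL unaffected 0.503 s, with a
#' total stride-to-stride plus between-subject spread of about 0.095 s.
#'
#' @param n_subjects_per_group subjects per cohort (default 6).
#' @param affected_side side of the reconstructed knee in the post-ACL
#'   cohort, `"left"` or `"right"`.
#' @param mean_gct_healthy,mean_gct_healthy_contra mean gait cycle time (s)
#'   of the healthy cohort on the affected-matched side and on the
#'   contralateral side.
#' @param mean_gct_acl_affected,mean_gct_acl_unaffected mean gait cycle
#'   time (s) of the post-ACL cohort on the affected / unaffected limb.
#' @param gct_sd_within stride-to-stride SD of gait cycle time (s).
#' @param gct_sd_between between-subject SD of the per-limb mean (s).
#' @param stance_fraction mean stance phase as a percentage of the gait
#'   cycle (in (0, 100)); `stance_fraction_sd` is its stride-level SD.
#' @param jerk_roughness_scale multiplier (>= 1) on the high-frequency
#'   acceleration content of the affected limb in the post-ACL cohort;
#'   1 means no roughness asymmetry.
#' @param noise_sd_accel,noise_sd_gyro white sensor noise SD (g, deg/s).
#' @param hf_accel_sd SD (g) of the band-limited (>6 Hz) acceleration
#'   roughness component present on every limb before scaling.
#' @param n_repetitions_per_subject repetitions per subject (default 10:
#'   five sidesteps to the left and five to the right).
#' @param n_strides strides per limb in each repetition.
#' @param sample_rate nominal sensor sampling rate (Hz).
#' @param clock_offset_range per-sensor clock offset drawn uniformly in
#'   +/- this value (s); set 0 for perfectly aligned clocks.
#' @param rate_error per-sensor relative sampling-rate error drawn
#'   uniformly in +/- this value.
#' @param time_jitter timestamp jitter drawn uniformly in +/- this value
#'   (s); kept below half a sample period so time stays monotone.
#' @param shank_yaw_range shank sensors are mounted with a yaw
#'   misalignment drawn uniformly in +/- this value (degrees).
#' @param squat_depth,squat_duration depth (g) and duration (s) of the
#'   synchronization squat's vertical-acceleration valley.
#' @param seed master seed; all generation is deterministic given it.
#' @return An object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_subjects_per_group = 6L,
                        affected_side = c("left", "right"),
                        mean_gct_healthy = 0.490,
                        mean_gct_healthy_contra = 0.509,
                        mean_gct_acl_affected = 0.514,
                        mean_gct_acl_unaffected = 0.503,
                        gct_sd_within = 0.091,
                        gct_sd_between = 0.025,
                        stance_fraction = 44.6,
                        stance_fraction_sd = 3,
                        jerk_roughness_scale = 1.5,
                        noise_sd_accel = 0.05,
                        noise_sd_gyro = 5,
                        hf_accel_sd = 0.12,
                        n_repetitions_per_subject = 10L,
                        n_strides = 8L,
                        sample_rate = 100,
                        clock_offset_range = 0.5,
                        rate_error = 0.01,
                        time_jitter = 0.002,
                        shank_yaw_range = 15,
                        squat_depth = 0.5,
                        squat_duration = 1.5,
                        seed = 1L) {
  affected_side <- match.arg(affected_side)
  spec <- list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    affected_side = affected_side,
    mean_gct_healthy = mean_gct_healthy,
    mean_gct_healthy_contra = mean_gct_healthy_contra,
    mean_gct_acl_affected = mean_gct_acl_affected,
    mean_gct_acl_unaffected = mean_gct_acl_unaffected,
    gct_sd_within = gct_sd_within,
    gct_sd_between = gct_sd_between,
    stance_fraction = stance_fraction,
    stance_fraction_sd = stance_fraction_sd,
    jerk_roughness_scale = jerk_roughness_scale,
    noise_sd_accel = noise_sd_accel,
    noise_sd_gyro = noise_sd_gyro,
    hf_accel_sd = hf_accel_sd,
    n_repetitions_per_subject = as.integer(n_repetitions_per_subject),
    n_strides = as.integer(n_strides),
    sample_rate = sample_rate,
    clock_offset_range = clock_offset_range,
    rate_error = rate_error,
    time_jitter = time_jitter,
    shank_yaw_range = shank_yaw_range,
    squat_depth = squat_depth,
    squat_duration = squat_duration,
    seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  num <- unlist(spec[vapply(spec, is.numeric, logical(1))])
  if (any(!is.finite(num))) stop("cohort_spec contains non-finite values")
  durs <- c(spec$mean_gct_healthy, spec$mean_gct_healthy_contra,
            spec$mean_gct_acl_affected, spec$mean_gct_acl_unaffected,
            spec$squat_duration)
  if (any(durs <= 0)) stop("all durations must be positive")
  if (spec$stance_fraction <= 0 || spec$stance_fraction >= 100)
    stop("stance_fraction must lie in (0, 100)")
  if (spec$n_repetitions_per_subject < 1L)
    stop("n_repetitions_per_subject must be >= 1")
  if (spec$n_strides < 1L) stop("n_strides must be >= 1")
  if (spec$jerk_roughness_scale < 0) stop("jerk_roughness_scale must be >= 0")
  invisible(spec)
}

# Mean gait cycle time for a cohort/limb cell, honouring the affected side.
gct_cell_mean <- function(spec, cohort, limb) {
  aff <- spec$affected_side
  if (cohort == "acl") {
    if (limb == aff) spec$mean_gct_acl_affected else spec$mean_gct_acl_unaffected
  } else {
    if (limb == aff) spec$mean_gct_healthy else spec$mean_gct_healthy_contra
  }
}

#' Draw per-subject random effects
#'
#' Subject-level offsets shared across a subject's repetitions: per-limb
#' deviations of the mean gait cycle time, a subject roughness multiplier,
#' and the mounting yaw of each shank sensor.
#'
#' @param spec a [cohort_spec()].
#' @param cohort `"healthy"` or `"acl"`.
#' @param seed integer seed for this subject.
#' @return A list of subject parameters.
#' @export
draw_subject_params <- function(spec, cohort, seed) {
  with_seed(seed, {
    list(
      cohort = cohort,
      gct_offset = stats::setNames(rnorm(2, 0, spec$gct_sd_between),
                                   c("left", "right")),
      roughness_subject = exp(rnorm(1, 0, 0.08)),
      shank_yaw = stats::setNames(
        runif(2, -spec$shank_yaw_range, spec$shank_yaw_range) * pi / 180,
        c("left", "right")),
      amp_scale = exp(rnorm(1, 0, 0.05)))
  })
}

# Per-limb stride sequence (event times in global seconds) for one
# repetition.  Stance fraction and cycle times are drawn per stride.
draw_stride_train <- function(spec, mean_gct, n_strides, start_time) {
  gct <- rnorm(n_strides, mean_gct, spec$gct_sd_within)
  gct <- pmin(pmax(gct, 0.30), 0.90)
  sf <- rnorm(n_strides, spec$stance_fraction, spec$stance_fraction_sd) / 100
  sf <- pmin(pmax(sf, 0.25), 0.65)
  ic <- start_time + c(0, cumsum(gct))
  data.frame(
    ic = ic[seq_len(n_strides)],
    tc = ic[seq_len(n_strides)] + sf * gct,
    next_ic = ic[seq_len(n_strides) + 1L],
    gct = gct, stp = sf * gct, swp = (1 - sf) * gct,
    stance_fraction = 100 * sf)
}

# Gaussian lobe helper.
gauss_lobe <- function(t, center, amp, width) {
  amp * exp(-(t - center)^2 / (2 * width^2))
}

# Mediolateral shank angular-rate template for one stride train: one
# dominant positive mid-swing lobe per stride plus smaller negative lobes
# at each initial and terminal contact.
gyro_x_template <- function(t, train, amp_ms = 300, amp_neg = 120,
                            width = 0.02) {
  g <- numeric(length(t))
  ics <- unique(c(train$ic, train$next_ic))
  for (u in ics) g <- g - gauss_lobe(t, u, amp_neg, width)
  for (u in train$tc) g <- g - gauss_lobe(t, u, amp_neg, width)
  # mid-swing: midpoint of the swing phase (tc -> next_ic)
  ms <- (train$tc + train$next_ic) / 2
  for (u in ms) g <- g + gauss_lobe(t, u, amp_ms, width)
  g
}

rot_z <- function(psi) {
  matrix(c(cos(psi), sin(psi), 0,
           -sin(psi), cos(psi), 0,
           0, 0, 1), 3, 3)
}

#' Generate one synthetic repetition
#'
#' Synthesizes the four sensor recordings of one run-and-sidestep
#' repetition in a common (global) time base, then samples each sensor on
#' its own imperfect clock.  The returned object carries the ground truth
#' (event times, clock offsets, shank yaw) used by oracle tests.
#'
#' @param spec a [cohort_spec()].
#' @param subject subject identifier (string).
#' @param cohort `"healthy"` or `"acl"`.
#' @param trial trial index, `1 <= trial <= n_repetitions_per_subject`.
#' @param direction sidestep direction, `"left"` or `"right"`.
#' @param subject_params optional output of [draw_subject_params()]; drawn
#'   from the spec seed when missing.
#' @param seed optional explicit seed for this repetition.
#' @param null_effect when `TRUE` the post-ACL asymmetries (gait cycle
#'   time shift and roughness multiplier) are suppressed so both cohorts
#'   share one distribution.
#' @return An object of class `repetition`: `sensors` (named list of four
#'   `imu_recording`s), metadata, and `truth`.
#' @export
generate_repetition <- function(spec, subject = "S1",
                                cohort = c("healthy", "acl"),
                                trial = 1L,
                                direction = c("left", "right"),
                                subject_params = NULL,
                                seed = NULL,
                                null_effect = FALSE) {
  validate_cohort_spec(spec)
  cohort <- match.arg(cohort)
  direction <- match.arg(direction)
  if (trial < 1L || trial > spec$n_repetitions_per_subject)
    stop("trial must be between 1 and n_repetitions_per_subject")
  sid_hash <- sum(utf8ToInt(subject))
  if (is.null(seed)) seed <- child_seed(spec$seed, sid_hash, trial)
  if (is.null(subject_params))
    subject_params <- draw_subject_params(spec, cohort,
                                          child_seed(spec$seed, sid_hash))
  eff_cohort <- if (null_effect) "healthy" else cohort
  with_seed(seed, {
    fine_rate <- 400
    squat_start <- 1.0
    run_start <- squat_start + spec$squat_duration + 1.0

    trains <- list()
    for (limb in c("left", "right")) {
      m <- gct_cell_mean(spec, eff_cohort, limb) +
        subject_params$gct_offset[[limb]]
      start <- run_start + if (limb == "right") {
        0.5 * gct_cell_mean(spec, eff_cohort, "left")
      } else 0
      trains[[limb]] <- draw_stride_train(spec, m, spec$n_strides, start)
    }
    t_end <- max(trains$left$next_ic, trains$right$next_ic)
    duration <- t_end + 1.5
    tg <- seq(0, duration, by = 1 / fine_rate)
    n <- length(tg)

    # sidestep transient: centred on a mid-train initial contact
    k_ss <- max(1L, min(spec$n_strides, spec$n_strides %/% 2L + 1L))
    sidestep_time <- trains$left$next_ic[k_ss]
    ss_sign <- if (direction == "left") -1 else 1
    ss_pulse <- ss_sign * gauss_lobe(tg, sidestep_time, 2.5, 0.08)

    squat <- numeric(n)
    in_sq <- tg >= squat_start & tg <= squat_start + spec$squat_duration
    squat[in_sq] <- -spec$squat_depth * 0.5 *
      (1 - cos(2 * pi * (tg[in_sq] - squat_start) / spec$squat_duration))

    amp <- subject_params$amp_scale
    roughness <- if (!null_effect && cohort == "acl")
      spec$jerk_roughness_scale else 1

    leg_signals <- list()
    for (limb in c("left", "right")) {
      tr <- trains[[limb]]
      gx <- gyro_x_template(tg, tr, amp_ms = 300 * amp, amp_neg = 120 * amp)
      # leg wobble shared by shank and thigh (hinge-joint constraint)
      f_step <- 1 / mean(tr$gct)
      wob_y <- 35 * sin(2 * pi * f_step * tg + runif(1, 0, 2 * pi)) +
        15 * sin(2 * pi * 1.7 * f_step * tg + runif(1, 0, 2 * pi))
      wob_z <- 25 * sin(2 * pi * f_step * tg + runif(1, 0, 2 * pi)) +
        10 * sin(2 * pi * 2.3 * f_step * tg + runif(1, 0, 2 * pi))

      az <- 1 + squat
      ay <- numeric(n)
      for (i in seq_len(nrow(tr))) {
        dt <- tg - tr$ic[i]
        imp <- dt >= 0 & dt < 0.4
        az[imp] <- az[imp] + 2.2 * amp * exp(-dt[imp] / 0.05) *
          sin(2 * pi * 12 * dt[imp])
        phase <- (tg - tr$ic[i]) / tr$gct[i]
        inp <- phase >= 0 & phase < 1
        ay[inp] <- ay[inp] + 0.5 * amp * sin(2 * pi * phase[inp])
      }
      # braking tail after the last contact
      dtail <- tg - max(tr$next_ic)
      tail_i <- dtail >= 0
      ay[tail_i] <- ay[tail_i] - 0.8 * exp(-dtail[tail_i] / 0.4)
      ax <- 0.2 * sin(2 * pi * f_step * tg + runif(1, 0, 2 * pi)) + ss_pulse

      limb_rough <- if (limb == spec$affected_side) roughness else 1
      hf_sd <- spec$hf_accel_sd * limb_rough * subject_params$roughness_subject
      hf <- replicate(3, zerophase_highpass(rnorm(n, 0, hf_sd), fine_rate, 6))
      leg_signals[[limb]] <- list(
        gx = gx, wob_y = wob_y, wob_z = wob_z,
        accel = cbind(ax, ay, az) + hf)
    }

    sensors <- list()
    offsets <- rate_errs <- stats::setNames(numeric(4), SENSOR_IDS)
    for (sid in SENSOR_IDS) {
      limb <- if (startsWith(sid, "left")) "left" else "right"
      seg <- if (endsWith(sid, "shank")) "shank" else "thigh"
      ls <- leg_signals[[limb]]
      gx <- if (seg == "shank") ls$gx else 0.45 * ls$gx
      gyro <- cbind(gx, ls$wob_y, ls$wob_z) +
        matrix(rnorm(3 * n, 0, spec$noise_sd_gyro), n, 3)
      accel <- ls$accel + matrix(rnorm(3 * n, 0, spec$noise_sd_accel), n, 3)
      if (seg == "shank") {
        R <- rot_z(subject_params$shank_yaw[[limb]])
        gyro <- gyro %*% t(R)
        accel <- accel %*% t(R)
      }
      accel <- pmin(pmax(accel, -16), 16)
      gyro <- pmin(pmax(gyro, -2000), 2000)

      delta <- runif(1, -spec$clock_offset_range, spec$clock_offset_range)
      rho <- runif(1, -spec$rate_error, spec$rate_error)
      offsets[sid] <- delta
      rate_errs[sid] <- rho
      k <- seq(0, floor(duration * spec$sample_rate))
      tg_k <- k / spec$sample_rate +
        runif(length(k), -spec$time_jitter, spec$time_jitter)
      tg_k <- pmin(pmax(tg_k, 0), max(tg))
      tg_k <- sort(tg_k)
      keep <- c(TRUE, diff(tg_k) > 1e-6)
      tg_k <- tg_k[keep]
      tl_k <- tg_k * (1 + rho) + delta
      samp <- function(col) approx(tg, col, xout = tg_k)$y
      sensors[[sid]] <- imu_recording(
        sensor_id = sid, t = tl_k,
        accel = apply(accel, 2, samp),
        gyro = apply(gyro, 2, samp),
        nominal_rate = spec$sample_rate)
    }

    truth <- list(
      events = trains,
      clock_offsets = offsets,
      rate_errors = rate_errs,
      shank_yaw = subject_params$shank_yaw,
      squat_center = squat_start + spec$squat_duration / 2,
      sidestep_time = sidestep_time,
      duration = duration)
    structure(list(sensors = sensors, subject = subject, cohort = cohort,
                   trial = as.integer(trial), direction = direction,
                   truth = truth),
              class = "repetition")
  })
}

#' Construct an IMU recording
#'
#' One sensor's time-stamped tri-axial acceleration and angular rate for
#' one repetition.  Axes follow the study convention: x mediolateral,
#' y anteroposterior, z vertical.
#'
#' @param sensor_id one of `left_shank`, `left_thigh`, `right_shank`,
#'   `right_thigh`.
#' @param t sample times (s), strictly increasing.
#' @param accel n x 3 acceleration matrix (g), |a| <= 16.
#' @param gyro n x 3 angular-rate matrix (deg/s), |w| <= 2000.
#' @param nominal_rate nominal sampling rate (Hz).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(sensor_id, t, accel, gyro, nominal_rate) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  colnames(accel) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  if (length(t) != nrow(accel) || length(t) != nrow(gyro))
    stop("t, accel and gyro must have matching lengths")
  d <- diff(t)
  if (any(d <= 0))
    stop(sprintf("sample times not strictly increasing at index %d",
                 which(d <= 0)[1] + 1L))
  if (any(abs(accel) > 16 + 1e-9)) stop("|accel| exceeds the 16 g range")
  if (any(abs(gyro) > 2000 + 1e-9)) stop("|gyro| exceeds the 2000 deg/s range")
  structure(list(sensor_id = sensor_id, t = t, accel = accel, gyro = gyro,
                 nominal_rate = nominal_rate),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s: %d samples, %.2f-%.2f s, nominal %g Hz\n",
              x$sensor_id, length(x$t), min(x$t), max(x$t), x$nominal_rate))
  invisible(x)
}

#' @export
print.repetition <- function(x, ...) {
  cat(sprintf("<repetition> subject %s (%s), trial %d, sidestep %s\n",
              x$subject, x$cohort, x$trial, x$direction))
  for (s in x$sensors) print(s)
  invisible(x)
}

#' Generate the full two-cohort dataset
#'
#' Balanced healthy and post-ACL cohorts with labelled repetitions (five
#' left and five right sidesteps per subject by default).
#'
#' @param spec a [cohort_spec()].
#' @param null_effect generate a null variant in which both groups share
#'   the healthy distribution (group label independent of the signals by
#'   construction).
#' @param dropout remove six repetitions (four post-ACL, two healthy),
#'   emulating recordings lost to hardware issues, leaving 58 healthy and
#'   56 post-ACL sets at the default sizes.
#' @param waveforms when `FALSE`, skip waveform synthesis and return
#'   ground-truth stride tables only (fast; used for stride-population
#'   statistics).
#' @return An object of class `imu_cohorts`: `repetitions` (list),
#'   `subjects` (data.frame with `subject`, `cohort`), and the spec.
#' @export
generate_cohorts <- function(spec, null_effect = FALSE, dropout = FALSE,
                             waveforms = TRUE) {
  validate_cohort_spec(spec)
  ns <- spec$n_subjects_per_group
  subjects <- data.frame(
    subject = c(sprintf("H%02d", seq_len(ns)), sprintf("A%02d", seq_len(ns))),
    cohort = rep(c("healthy", "acl"), each = ns),
    stringsAsFactors = FALSE)
  nrep <- spec$n_repetitions_per_subject
  directions <- rep(c("left", "right"), length.out = nrep,
                    each = max(1L, nrep %/% 2L))[seq_len(nrep)]
  reps <- list()
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects$subject[i]; coh <- subjects$cohort[i]
    sp <- draw_subject_params(spec, coh,
                              child_seed(spec$seed, sum(utf8ToInt(sub))))
    for (tr in seq_len(nrep)) {
      rep_obj <- if (waveforms) {
        generate_repetition(spec, sub, coh, tr, directions[tr],
                            subject_params = sp, null_effect = null_effect)
      } else {
        generate_truth_only(spec, sub, coh, tr, directions[tr], sp,
                            null_effect = null_effect)
      }
      reps[[sprintf("%s_t%02d", sub, tr)]] <- rep_obj
    }
  }
  if (dropout) {
    drop_n <- c(acl = 4L, healthy = 2L)
    cohort_of <- vapply(reps, function(r) r$cohort, character(1))
    drop_idx <- with_seed(child_seed(spec$seed, 999L), {
      c(sample(which(cohort_of == "acl"), drop_n["acl"]),
        sample(which(cohort_of == "healthy"), drop_n["healthy"]))
    })
    reps <- reps[-drop_idx]
  }
  structure(list(repetitions = reps, subjects = subjects, spec = spec,
                 null_effect = null_effect),
            class = "imu_cohorts")
}

# Truth-only repetition: stride trains without waveform synthesis.
generate_truth_only <- function(spec, subject, cohort, trial, direction,
                                subject_params, null_effect = FALSE) {
  seed <- child_seed(spec$seed, sum(utf8ToInt(subject)), trial)
  eff_cohort <- if (null_effect) "healthy" else cohort
  with_seed(seed, {
    run_start <- 1.0 + spec$squat_duration + 1.0
    trains <- list()
    for (limb in c("left", "right")) {
      m <- gct_cell_mean(spec, eff_cohort, limb) +
        subject_params$gct_offset[[limb]]
      start <- run_start + if (limb == "right") {
        0.5 * gct_cell_mean(spec, eff_cohort, "left")
      } else 0
      trains[[limb]] <- draw_stride_train(spec, m, spec$n_strides, start)
    }
    structure(list(sensors = NULL, subject = subject, cohort = cohort,
                   trial = as.integer(trial), direction = direction,
                   truth = list(events = trains)),
              class = "repetition")
  })
}

#' @export
print.imu_cohorts <- function(x, ...) {
  cat(sprintf("<imu_cohorts> %d subjects (%d per group), %d repetitions%s\n",
              nrow(x$subjects), x$spec$n_subjects_per_group,
              length(x$repetitions),
              if (isTRUE(x$null_effect)) " [null variant]" else ""))
  invisible(x)
}

#' Ground-truth stride population of a dataset
#'
#' Flattens the generator's per-repetition ground-truth stride trains into
#' one data frame, one row per stride, with the six temporal parameters
#' computed from the programmed event times.
#'
#' @param cohorts an `imu_cohorts` object.
#' @return data.frame with `subject`, `cohort`, `limb`, `gct`, `stp`,
#'   `swp`, `rstp`, `rswp`, `cadence`.
#' @export
stride_population <- function(cohorts) {
  out <- list()
  for (nm in names(cohorts$repetitions)) {
    r <- cohorts$repetitions[[nm]]
    for (limb in c("left", "right")) {
      tr <- r$truth$events[[limb]]
      out[[paste(nm, limb)]] <- data.frame(
        subject = r$subject, cohort = r$cohort, limb = limb,
        gct = tr$gct, stp = tr$stp, swp = tr$swp,
        rstp = 100 * tr$stp / tr$gct, rswp = 100 * tr$swp / tr$gct,
        cadence = 1 / tr$gct, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
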