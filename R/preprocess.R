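# Temporal alignment and frame consistency of raw multi-sensor streams:
# uniform resampling onto a common grid, squat-based synchronization, and
# rotation of the shank sensors so their x-axis is the mediolateral
# (knee-flexion) axis.

#' Resample a recording onto a uniform grid
#'
#' Piecewise-linear interpolation of every channel onto an arithmetic time
#' grid at `target_rate`, spanning the input's time range.  The output has
#' `floor(span * rate) + 1` samples.
#'
#' @param rec an `imu_recording`.
#' @param target_rate target sampling rate (Hz).
#' @return A uniformly sampled `imu_recording`.
#' @export
resample_uniform <- function(rec, target_rate) {
  t <- rec$t
  if (length(t) < 2L) stop("need at least 2 samples to resample")
  d <- diff(t)
  if (any(d <= 0))
    stop(sprintf("sample times not strictly increasing at index %d",
                 which(d <= 0)[1] + 1L))
  span <- t[length(t)] - t[1]
  grid <- t[1] + seq(0, floor(span * target_rate)) / target_rate
  interp <- function(col) approx(t, col, xout = grid)$y
  imu_recording(rec$sensor_id, grid,
                apply(rec$accel, 2, interp),
                apply(rec$gyro, 2, interp),
                nominal_rate = target_rate)
}

#' Detect the synchronization squat and per-sensor offsets
#'
#' The squat signature is the valley of the 1 Hz low-passed vertical
#' acceleration in the leading window of each recording; its time is
#' refined to sub-sample precision as the deficit-weighted centroid of
#' the valley.  Offsets are reported relative
#' to the first recording (the reference, offset 0); subtracting each
#' sensor's offset from its time stamps makes the squat features coincide.
#'
#' @param recordings list of `imu_recording`s (reference first).
#' @param window leading window (s) searched for the squat.
#' @param lowpass_cutoff low-pass cutoff (Hz) applied before the search.
#' @param min_depth minimum depth (g) of the valley below the window's
#'   median vertical acceleration; shallower valleys raise a sync-failure
#'   error.
#' @return Named numeric vector of per-sensor offsets (s), with attribute
#'   `feature_times` (the detected squat times in each sensor's clock).
#' @export
detect_squat_sync <- function(recordings, window = 5, lowpass_cutoff = 1,
                              min_depth = 0.2) {
  feat <- vapply(recordings, function(rec) {
    u <- resample_uniform(rec, rec$nominal_rate)
    idx <- u$t - u$t[1] <= window
    if (sum(idx) < 20L) stop("leading window too short for squat search")
    # filter the full series, then crop: keeps the window free of filter
    # edge transients
    az <- zerophase_lowpass(u$accel[, "az"], u$nominal_rate,
                            lowpass_cutoff, order = 2)[idx]
    i <- which.min(az)
    base <- median(az)
    depth <- base - az[i]
    if (depth < min_depth)
      stop(sprintf(
        "sync failure: no squat signature in %s (valley depth %.3f g < %.3f g)",
        rec$sensor_id, depth, min_depth))
    # deficit-weighted centroid of the valley below 40% depth: robust to
    # noise on the wide, symmetric squat dip
    level <- base - 0.4 * depth
    below <- az < level
    lo <- i; while (lo > 1L && below[lo - 1L]) lo <- lo - 1L
    hi <- i; while (hi < length(az) && below[hi + 1L]) hi <- hi + 1L
    w <- level - az[lo:hi]
    sum(u$t[idx][lo:hi] * w) / sum(w)
  }, numeric(1))
  ids <- vapply(recordings, function(r) r$sensor_id, character(1))
  offsets <- stats::setNames(feat - feat[1], ids)
  attr(offsets, "feature_times") <- stats::setNames(feat, ids)
  offsets
}

# Hinge-axis cost from the functional joint constraint: a hinge joint
# constrains the two segments' angular rates to differ only about the
# joint axis, so the magnitudes of
# the components perpendicular to the axis agree.  cost(j) = sum over t of
# (|w_shank x j| - |w_thigh x j_thigh|)^2 for unit axes.
hinge_cost <- function(j, gs, perp_thigh) {
  px <- gs[, 2] * j[3] - gs[, 3] * j[2]
  py <- gs[, 3] * j[1] - gs[, 1] * j[3]
  pz <- gs[, 1] * j[2] - gs[, 2] * j[1]
  e <- sqrt(px^2 + py^2 + pz^2) - perp_thigh
  sum(e^2)
}

# Damped Gauss-Newton on the unit sphere for the shank hinge axis,
# multi-started from the six coordinate axis seeds.
estimate_hinge_axis <- function(gs, perp_thigh, max_iter = 200,
                                tol = 1e-10) {
  seeds <- rbind(diag(3), -diag(3))
  best <- NULL
  for (s in seq_len(nrow(seeds))) {
    j <- seeds[s, ]
    cost <- hinge_cost(j, gs, perp_thigh)
    lambda <- 1e-3
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      px <- gs[, 2] * j[3] - gs[, 3] * j[2]
      py <- gs[, 3] * j[1] - gs[, 1] * j[3]
      pz <- gs[, 1] * j[2] - gs[, 2] * j[1]
      nrm <- sqrt(px^2 + py^2 + pz^2)
      ok <- nrm > 1e-9
      r <- nrm[ok] - perp_thigh[ok]
      # d|w x j|/dj = ((w x j) x w) / |w x j|
      cx <- (py * gs[, 3] - pz * gs[, 2])[ok] / nrm[ok]
      cy <- (pz * gs[, 1] - px * gs[, 3])[ok] / nrm[ok]
      cz <- (px * gs[, 2] - py * gs[, 1])[ok] / nrm[ok]
      J <- cbind(cx, cy, cz)
      g <- crossprod(J, r)
      g_tan <- g - sum(g * j) * j   # tangent component on the unit sphere
      if (sqrt(sum(g_tan^2)) < 1e-8 * max(cost, 1)) { converged <- TRUE; break }
      A <- crossprod(J) + lambda * diag(3)
      step <- tryCatch(solve(A, -g), error = function(e) NULL)
      if (is.null(step)) break
      j_new <- j + as.numeric(step)
      j_new <- j_new / sqrt(sum(j_new^2))
      cost_new <- hinge_cost(j_new, gs, perp_thigh)
      if (cost_new < cost) {
        dc <- cost - cost_new
        j <- j_new
        cost <- cost_new
        lambda <- max(lambda / 3, 1e-10)
        if (dc < tol * max(cost, 1)) { converged <- TRUE; break }
      } else {
        lambda <- lambda * 10
        # stalled at the cost floor: a (possibly noisy) local optimum
        if (lambda > 1e8) { converged <- TRUE; break }
      }
    }
    if (!converged) {
      # slow creep up to the iteration cap: accept if the gradient has
      # effectively vanished
      px <- gs[, 2] * j[3] - gs[, 3] * j[2]
      py <- gs[, 3] * j[1] - gs[, 1] * j[3]
      pz <- gs[, 1] * j[2] - gs[, 2] * j[1]
      nrm <- sqrt(px^2 + py^2 + pz^2)
      ok <- nrm > 1e-9
      r <- nrm[ok] - perp_thigh[ok]
      cx <- (py * gs[, 3] - pz * gs[, 2])[ok] / nrm[ok]
      cy <- (pz * gs[, 1] - px * gs[, 3])[ok] / nrm[ok]
      cz <- (px * gs[, 2] - py * gs[, 1])[ok] / nrm[ok]
      g <- crossprod(cbind(cx, cy, cz), r)
      g_tan <- g - sum(g * j) * j
      converged <- sqrt(sum(g_tan^2)) < 1e-5 * max(cost, 1)
    }
    cand <- list(axis = j, cost = cost, converged = converged)
    # prefer converged candidates; fall back to the lowest cost overall
    if (is.null(best) ||
        (cand$converged && !best$converged) ||
        (cand$converged == best$converged && cand$cost < best$cost))
      best <- cand
  }
  best
}

#' Rotate a shank recording into the mediolateral frame
#'
#' Estimates the knee-flexion (hinge) axis in the shank sensor frame from
#' the paired shank/thigh gyroscopes, then rotates the shank data about
#' the vertical so its x-axis is the mediolateral axis.  The sign is fixed
#' so the dominant mid-swing angular rate about x is positive.
#'
#' @param shank,thigh synchronized, uniformly sampled `imu_recording`s of
#'   one leg containing flexion-dominant motion.
#' @param max_iter,tol Gauss-Newton iteration cap and relative tolerance
#'   on the cost decrease.
#' @param max_rel_cost identifiability threshold: the fit is flagged
#'   low-confidence when the optimal cost exceeds this fraction of the
#'   cost at orthogonal candidate axes (errors unless `strict = FALSE`).
#' @param strict raise errors on failed/low-confidence estimation (when
#'   `FALSE`, a flagged result is returned instead).
#' @return list with `recording` (rotated shank), `rotation` (3x3,
#'   orthonormal), `axis`, `cost`, `confidence`, `low_confidence`.
#' @export
align_shank_frame <- function(shank, thigh, max_iter = 200, tol = 1e-10,
                              max_rel_cost = 0.25, strict = TRUE) {
  gs <- shank$gyro
  gt <- thigh$gyro
  n <- min(nrow(gs), nrow(gt))
  gs <- gs[seq_len(n), , drop = FALSE]
  gt <- gt[seq_len(n), , drop = FALSE]
  # thigh sensors are mounted mediolaterally: its hinge axis is x
  perp_thigh <- sqrt(gt[, "gy"]^2 + gt[, "gz"]^2)
  fit <- estimate_hinge_axis(gs, perp_thigh, max_iter, tol)
  if (!fit$converged && strict)
    stop(sprintf("hinge-axis estimation failed to converge (final cost %.4g)",
                 fit$cost))
  # identifiability: a genuine hinge axis beats orthogonal candidate axes
  # by a wide cost margin; for axis-free data (e.g. pure noise) the cost
  # is nearly isotropic
  j <- fit$axis
  o1 <- if (abs(j[3]) < 0.9) c(-j[2], j[1], 0) else c(1, 0, 0)
  o1 <- o1 / sqrt(sum(o1^2))
  o2 <- c(j[2] * o1[3] - j[3] * o1[2], j[3] * o1[1] - j[1] * o1[3],
          j[1] * o1[2] - j[2] * o1[1])
  orth_cost <- mean(c(hinge_cost(o1, gs, perp_thigh),
                      hinge_cost(o2, gs, perp_thigh)))
  rel_cost <- fit$cost / max(orth_cost, 1e-12)
  low_conf <- rel_cost > max_rel_cost || abs(fit$axis[3]) > 0.5
  if (low_conf && strict)
    stop(sprintf(
      "low-confidence hinge axis (cost ratio vs orthogonal axes %.3f, |z component| %.2f)",
      rel_cost, abs(fit$axis[3])))
  # yaw that brings the axis' horizontal component onto +x
  psi <- atan2(fit$axis[2], fit$axis[1])
  R <- t(rot_z(psi))   # rotates measured vectors by -psi about z
  gyro <- gs %*% t(R)
  # sign convention: dominant mid-swing lobes about x are positive
  gx <- gyro[, 1]
  big <- abs(gx) > quantile(abs(gx), 0.9)
  if (sum(gx[big]^3) < 0) {
    R <- rot_z(pi) %*% R
    gyro <- gs %*% t(R)
  }
  accel <- shank$accel %*% t(R)
  rec <- imu_recording(shank$sensor_id, shank$t, accel, gyro,
                       shank$nominal_rate)
  list(recording = rec, rotation = R, axis = fit$axis, cost = fit$cost,
       confidence = 1 - rel_cost, low_confidence = low_conf)
}

#' Preprocess one repetition end to end
#'
#' Resamples all four sensors, synchronizes them on the squat signature,
#' places them on a shared uniform time base, and rotates each shank
#' sensor into the mediolateral frame using its thigh pair.
#'
#' @param rep a `repetition`.
#' @param target_rate common sampling rate (Hz).
#' @param sync_window,min_depth squat-search parameters, see
#'   [detect_squat_sync()].
#' @param align rotate the shank frames (disable for raw-frame work).
#' @return An object of class `aligned_repetition`: `signals` (named list
#'   of uniformly sampled `imu_recording`s on one shared grid), `rate`,
#'   `offsets`, `rotations`, and the repetition metadata.
#' @export
preprocess_repetition <- function(rep, target_rate = 100, sync_window = 5,
                                  min_depth = 0.2, align = TRUE) {
  recs <- lapply(rep$sensors, resample_uniform, target_rate = target_rate)
  offsets <- detect_squat_sync(recs, window = sync_window,
                               min_depth = min_depth)
  shifted <- Map(function(r, o) {
    imu_recording(r$sensor_id, r$t - o, r$accel, r$gyro, r$nominal_rate)
  }, recs, offsets[names(recs)])
  t0 <- max(vapply(shifted, function(r) r$t[1], numeric(1)))
  t1 <- min(vapply(shifted, function(r) r$t[length(r$t)], numeric(1)))
  if (t1 - t0 < 1) stop("sensors share less than 1 s of common time")
  grid <- t0 + seq(0, floor((t1 - t0) * target_rate)) / target_rate
  common <- lapply(shifted, function(r) {
    interp <- function(col) approx(r$t, col, xout = grid)$y
    imu_recording(r$sensor_id, grid, apply(r$accel, 2, interp),
                  apply(r$gyro, 2, interp), target_rate)
  })
  rotations <- list()
  if (align) {
    for (leg in c("left", "right")) {
      sh <- paste0(leg, "_shank"); th <- paste0(leg, "_thigh")
      al <- align_shank_frame(common[[sh]], common[[th]])
      common[[sh]] <- al$recording
      rotations[[sh]] <- al$rotation
    }
  }
  structure(list(signals = common, rate = target_rate, offsets = offsets,
                 rotations = rotations, subject = rep$subject,
                 cohort = rep$cohort, trial = rep$trial,
                 direction = rep$direction, truth = rep$truth),
            class = "aligned_repetition")
}

#' @export
print.aligned_repetition <- function(x, ...) {
  cat(sprintf(
    "<aligned_repetition> subject %s (%s), trial %d: %d sensors @ %g Hz, %d samples\n",
    x$subject, x$cohort, x$trial, length(x$signals), x$rate,
    length(x$signals[[1]]$t)))
  invisible(x)
}
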