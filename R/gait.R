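# Gait event detection from the mediolateral shank angular rate and the
# six temporal parameters per step.
#
# Event operators: mid-swing is a positive peak of the mediolateral shank
# angular rate above an adaptive threshold (0.6 x the 95th percentile of
# the positive part, with a 0.3 s refractory period); terminal contact is
# the last negative peak preceding each mid-swing and initial contact the
# first negative peak following it.  A validity filter discards strides
# whose parameters are outside physiological bounds (run-up, braking and
# sidestep artifacts).

#' Detect gait events in a mediolateral shank angular-rate series
#'
#' @param gyro_x mediolateral angular-rate series (deg/s), aligned and
#'   uniformly sampled.
#' @param rate sampling rate (Hz).
#' @param t optional sample times (s); defaults to `(0:(n-1))/rate`.
#' @param threshold_frac mid-swing threshold as a fraction of the 95th
#'   percentile of the positive part of the series.
#' @param refractory minimum separation (s) between mid-swing peaks.
#' @param neg_threshold_frac negative peaks shallower than this fraction
#'   of the 95th percentile of the negative part are ignored.
#' @param smooth_cutoff low-pass cutoff (Hz) applied before detection
#'   (`NULL` to disable).
#' @param refine parabolic sub-sample refinement of event times.
#' @return data.frame with one row per detected mid-swing: `ms`,
#'   `tc_before`, `ic_after` (s; `NA` when no qualifying negative peak
#'   exists on that side).  Zero rows when no stride is found.
#' @export
detect_gait_events <- function(gyro_x, rate, t = NULL,
                               threshold_frac = 0.6, refractory = 0.3,
                               neg_threshold_frac = 0.5,
                               smooth_cutoff = 15, refine = TRUE) {
  n <- length(gyro_x)
  if (is.null(t)) t <- seq(0, n - 1) / rate
  if (n < 5L) return(empty_events())
  x <- gyro_x
  if (!is.null(smooth_cutoff) && smooth_cutoff < rate / 2)
    x <- zerophase_lowpass(x, rate, smooth_cutoff, order = 2)
  pos <- x[x > 0]
  if (length(pos) < 3L) return(empty_events())
  thr <- threshold_frac * quantile(pos, 0.95, names = FALSE)
  if (thr <= 0) return(empty_events())
  cand <- local_maxima(x)
  cand <- cand[x[cand] >= thr]
  if (length(cand) == 0L) return(empty_events())
  # refractory period: scan in time order, keep the taller of two peaks
  # closer than `refractory`
  keep <- cand[1]
  for (i in cand[-1]) {
    last <- keep[length(keep)]
    if (t[i] - t[last] >= refractory) keep <- c(keep, i)
    else if (x[i] > x[last]) keep[length(keep)] <- i
  }
  mins <- local_minima(x)
  neg <- x[x < 0]
  neg_thr <- if (length(neg) >= 3L)
    -neg_threshold_frac * quantile(-neg, 0.95, names = FALSE) else 0
  mins <- mins[x[mins] < min(neg_thr, 0)]
  ev_time <- function(i) if (refine) refine_parabolic(t, x, i) else t[i]
  rows <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    lo <- if (k > 1L) keep[k - 1L] else 0L
    hi <- if (k < length(keep)) keep[k + 1L] else n + 1L
    before <- mins[mins > lo & mins < i]
    after <- mins[mins > i & mins < hi]
    data.frame(
      ms = ev_time(i),
      tc_before = if (length(before)) ev_time(before[length(before)]) else NA_real_,
      ic_after = if (length(after)) ev_time(after[1]) else NA_real_)
  })
  do.call(rbind, rows)
}

empty_events <- function() {
  data.frame(ms = numeric(0), tc_before = numeric(0), ic_after = numeric(0))
}

#' Temporal gait parameters from detected events
#'
#' Builds one row per complete initial-contact-to-initial-contact cycle:
#' gait cycle time (GCT), stance phase (STP, initial to terminal contact),
#' swing phase (SWP), their relative percentages, and cadence (1/GCT).
#' Strides failing the validity filter (GCT or relative stance phase
#' outside physiological bounds, as happens around the run's start/stop
#' and the sidestep transient) are discarded.
#'
#' @param events event data.frame from [detect_gait_events()].
#' @param limb `"left"` or `"right"`.
#' @param gct_range,rstp_range validity-filter bounds on GCT (s) and
#'   relative stance phase (%).
#' @return A `stride_table` data.frame: `limb`, `initial_contact`,
#'   `terminal_contact`, `next_initial_contact`, `gct`, `stp`, `swp`,
#'   `rstp`, `rswp`, `cadence`.  When no valid stride exists an empty
#'   table is returned with attribute `no_valid_strides = TRUE` and a
#'   warning.
#' @export
compute_stride_table <- function(events, limb = "left",
                                 gct_range = c(0.2, 1.2),
                                 rstp_range = c(20, 80)) {
  if (nrow(events) == 0L) return(empty_stride_table(limb))
  if (is.unsorted(events$ms, strictly = TRUE))
    stop("events must be ordered by mid-swing time")
  rows <- list()
  for (k in seq_len(nrow(events) - 1L)) {
    ic <- events$ic_after[k]
    tc <- events$tc_before[k + 1L]
    nic <- events$ic_after[k + 1L]
    if (anyNA(c(ic, tc, nic))) next
    if (!(ic < tc && tc < nic)) next
    gct <- nic - ic
    stp <- tc - ic
    rows[[length(rows) + 1L]] <- data.frame(
      limb = limb, initial_contact = ic, terminal_contact = tc,
      next_initial_contact = nic, gct = gct, stp = stp, swp = gct - stp,
      rstp = 100 * stp / gct, rswp = 100 * (gct - stp) / gct,
      cadence = 1 / gct, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_stride_table(limb)
  ok <- out$gct >= gct_range[1] & out$gct <= gct_range[2] &
    out$rstp >= rstp_range[1] & out$rstp <= rstp_range[2]
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning("no valid strides detected")
    attr(out, "no_valid_strides") <- TRUE
  }
  class(out) <- c("stride_table", "data.frame")
  out
}

empty_stride_table <- function(limb) {
  out <- data.frame(limb = character(0), initial_contact = numeric(0),
                    terminal_contact = numeric(0),
                    next_initial_contact = numeric(0), gct = numeric(0),
                    stp = numeric(0), swp = numeric(0), rstp = numeric(0),
                    rswp = numeric(0), cadence = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("stride_table", "data.frame")
  out
}

#' Gait analysis of an aligned repetition
#'
#' Runs event detection on both shank sensors' mediolateral angular rate
#' and stacks the per-limb stride tables.
#'
#' @param arep an `aligned_repetition`.
#' @param ... passed on to [detect_gait_events()] and
#'   [compute_stride_table()].
#' @return A `stride_table` covering both limbs.
#' @export
gait_analysis <- function(arep, ...) {
  dots <- list(...)
  det_args <- dots[names(dots) %in%
    c("threshold_frac", "refractory", "neg_threshold_frac",
      "smooth_cutoff", "refine")]
  tab_args <- dots[names(dots) %in% c("gct_range", "rstp_range")]
  out <- list()
  for (limb in c("left", "right")) {
    rec <- arep$signals[[paste0(limb, "_shank")]]
    ev <- do.call(detect_gait_events,
                  c(list(rec$gyro[, "gx"], rate = arep$rate, t = rec$t),
                    det_args))
    out[[limb]] <- suppressWarnings(
      do.call(compute_stride_table, c(list(ev, limb = limb), tab_args)))
  }
  res <- rbind(out$left, out$right)
  class(res) <- c("stride_table", "data.frame")
  res
}

#' @export
print.stride_table <- function(x, ...) {
  cat(sprintf("<stride_table> %d strides (%d left, %d right)\n", nrow(x),
              sum(x$limb == "left"), sum(x$limb == "right")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), digits = 4)
  invisible(x)
}

#' Per-group/limb summary of gait parameters
#'
#' Mean and SD of each temporal parameter, mirroring a descriptive
#' statistics table by cohort and limb.
#'
#' @param strides data.frame with at least `cohort`, `limb` and the six
#'   parameter columns (`gct`, `stp`, `swp`, `rstp`, `rswp`, `cadence`).
#' @return data.frame of means and SDs per cohort x limb cell plus
#'   marginals.
#' @export
summarize_gait <- function(strides) {
  params <- c("gct", "stp", "swp", "rstp", "rswp", "cadence")
  cells <- expand.grid(cohort = c(unique(strides$cohort), "overall"),
                       limb = c("left", "right", "total"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- strides
    if (cells$cohort[i] != "overall") sel <- sel[sel$cohort == cells$cohort[i], ]
    if (cells$limb[i] != "total") sel <- sel[sel$limb == cells$limb[i], ]
    stats <- lapply(params, function(p) {
      c(mean = mean(sel[[p]]), sd = sd(sel[[p]]))
    })
    data.frame(cohort = cells$cohort[i], limb = cells$limb[i], n = nrow(sel),
               t(unlist(stats)), stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("cohort", "limb", "n",
                  as.vector(t(outer(params, c("mean", "sd"), paste, sep = "_"))))
  out
}
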