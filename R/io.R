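# Plain-text external interfaces: the per-sensor CSV dialect
# (t,ax,ay,az,gx,gy,gz), dataset manifest, ground-truth events, stride
# tables, feature matrices, and JSON alignment/registry reports.

#' Write one sensor recording as CSV
#'
#' Columns `t,ax,ay,az,gx,gy,gz` (seconds, g, deg/s).
#'
#' @param rec an `imu_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  df <- data.frame(t = rec$t, rec$accel, rec$gyro, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sensor recording from CSV
#'
#' @param path CSV with columns `t,ax,ay,az,gx,gy,gz`.
#' @param sensor_id sensor identifier to attach.
#' @param nominal_rate nominal sampling rate (Hz).
#' @return an `imu_recording`.
#' @export
read_imu_csv <- function(path, sensor_id, nominal_rate = 100) {
  df <- read.csv(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df)))
    stop(sprintf("missing column(s): %s",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  imu_recording(sensor_id, df$t, as.matrix(df[c("ax", "ay", "az")]),
                as.matrix(df[c("gx", "gy", "gz")]), nominal_rate)
}

#' Write a dataset to a directory of CSV files
#'
#' One CSV per sensor per repetition, a manifest
#' (`subject,cohort,trial,direction,sensor,path`), and a ground-truth
#' events CSV (`subject,trial,limb,ic,tc,next_ic`).
#'
#' @param cohorts an `imu_cohorts` object (with waveforms).
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohorts_csv <- function(cohorts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(); events <- list()
  for (nm in names(cohorts$repetitions)) {
    r <- cohorts$repetitions[[nm]]
    for (sid in names(r$sensors)) {
      fn <- sprintf("%s_%s.csv", nm, sid)
      write_imu_csv(r$sensors[[sid]], file.path(dir, fn))
      manifest[[paste(nm, sid)]] <- data.frame(
        subject = r$subject, cohort = r$cohort, trial = r$trial,
        direction = r$direction, sensor = sid, path = fn,
        stringsAsFactors = FALSE)
    }
    for (limb in c("left", "right")) {
      tr <- r$truth$events[[limb]]
      events[[paste(nm, limb)]] <- data.frame(
        subject = r$subject, trial = r$trial, limb = limb,
        ic = tr$ic, tc = tr$tc, next_ic = tr$next_ic)
    }
  }
  manifest <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(do.call(rbind, c(events, list(make.row.names = FALSE))),
            file.path(dir, "ground_truth_events.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write an alignment report as JSON
#'
#' Per-sensor sync offsets and shank rotation matrices of a preprocessed
#' repetition.
#'
#' @param arep an `aligned_repetition`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(arep, path) {
  rep_list <- list(
    subject = arep$subject, trial = arep$trial, rate = arep$rate,
    offsets = as.list(arep$offsets),
    rotations = lapply(arep$rotations, function(R) unclass(as.data.frame(R))))
  jsonlite::write_json(rep_list, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a stride table as CSV
#' @param strides a `stride_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stride_csv <- function(strides, path) {
  write.csv(as.data.frame(strides), path, row.names = FALSE)
  invisible(path)
}

#' Write the feature matrix (and its registry manifest) to disk
#'
#' @param features feature data.frame from [feature_matrix()].
#' @param path output CSV.
#' @param registry optional [feature_registry()]; when given, a JSON
#'   manifest is written next to the CSV.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path, registry = NULL) {
  write.csv(features, path, row.names = FALSE)
  if (!is.null(registry)) {
    jsonlite::write_json(
      list(sensors = registry$sensors,
           n_features = registry_size(registry),
           gravity_cutoff = registry$gravity_cutoff,
           sampen_m = registry$sampen_m,
           sampen_r_frac = registry$sampen_r_frac,
           sparc_fc = registry$sparc_fc,
           feature_names = setdiff(names(features), META_COLS)),
      sub("\\.csv$", "_registry.json", path), auto_unbox = TRUE)
  }
  invisible(path)
}
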