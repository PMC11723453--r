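#' @useDynLib rowkinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor rnorm runif sd t.test setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Channel vocabularies per condition. Forces/powers are measurement targets,
# never model inputs (see features blacklist).
.rk_required_channels <- list(
  ergometer = list(
    sensors = c("X_handle", "X_chest", "X_seat", "F_handle", "F_feet")
  ),
  boat = list(
    oars = c("theta_port", "theta_starboard",
             "Fg_x_port", "Fg_x_starboard", "Fg_y_port", "Fg_y_starboard"),
    stretcher = c("F_feet_x"),
    gps = c("V_boat"),
    boat_imu = c("A_boat"),
    imu_pelvis = c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z", "tilt"),
    imu_lumbar = c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z"),
    imu_thoracic = c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  )
)

#' Construct a uniformly sampled multichannel sensor stream
#'
#' All values are SI (m, m/s, m/s^2, rad, rad/s, N). Indexing is 0-based
#' half-open at the cycle level; within R, columns of `values` are channels.
#'
#' @param values numeric matrix, `n_samples x n_channels`.
#' @param sample_rate_hz sampling rate in Hz (> 0).
#' @param channels character vector of channel names, one per column.
#' @param t0_s session-relative start time of the first sample, seconds.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(values, sample_rate_hz, channels, t0_s = 0) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 2,
            length(channels) == ncol(values),
            is.numeric(sample_rate_hz), sample_rate_hz > 0)
  colnames(values) <- channels
  structure(list(values = values, sample_rate_hz = sample_rate_hz,
                 channels = as.character(channels), t0_s = t0_s),
            class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d samples x %d channels @ %g Hz (t0 = %g s)\n",
              nrow(x$values), ncol(x$values), x$sample_rate_hz, x$t0_s))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Sample times of a sensor stream
#' @param stream a [sensor_stream].
#' @return Numeric vector of session-relative sample times, seconds.
#' @export
stream_time <- function(stream) {
  stream$t0_s + (seq_len(nrow(stream$values)) - 1) / stream$sample_rate_hz
}

#' Extract one channel of a sensor stream
#' @param stream a [sensor_stream].
#' @param name channel name.
#' @return Numeric vector.
#' @export
stream_channel <- function(stream, name) {
  if (!name %in% stream$channels) stop("no channel '", name, "'")
  stream$values[, name]
}

#' Construct a subject profile
#'
#' @param subject_id character identifier.
#' @param height_m standing height in metres, in (1.0, 2.5).
#' @param mass_kg body mass in kg, in (30, 150).
#' @param condition `"ergometer"` or `"boat"`.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, height_m, mass_kg, condition) {
  condition <- match.arg(condition, c("ergometer", "boat"))
  stopifnot(height_m > 1.0, height_m < 2.5, mass_kg > 30, mass_kg < 150)
  structure(list(subject_id = as.character(subject_id), height_m = height_m,
                 mass_kg = mass_kg, condition = condition),
            class = "subject_profile")
}

#' Construct a rowing cycle (finish-to-finish slice)
#'
#' Indices are 0-based and half-open: the cycle covers samples
#' `[start_idx, end_idx)` of the session stream. The catch is the reference
#' signal minimum between the two finish events; the drive-phase window
#' (when present) is the force-threshold-based effective drive phase.
#'
#' @param subject_id subject identifier.
#' @param start_idx,end_idx 0-based half-open slice bounds into the stream.
#' @param catch_idx 0-based catch sample index, `start_idx < catch_idx < end_idx`.
#' @param stroke_rate_spm instantaneous stroke rate, strokes/min.
#' @param drive_start_idx,drive_end_idx optional effective-drive window.
#' @param scalars named list of per-cycle scalars.
#' @return An object of class `rowing_cycle`.
#' @export
rowing_cycle <- function(subject_id, start_idx, end_idx, catch_idx,
                         stroke_rate_spm, drive_start_idx = NULL,
                         drive_end_idx = NULL, scalars = list()) {
  stopifnot(start_idx < catch_idx, catch_idx < end_idx)
  if (!is.null(drive_start_idx)) {
    stopifnot(start_idx <= drive_start_idx, drive_start_idx < drive_end_idx,
              drive_end_idx <= end_idx)
  }
  structure(list(subject_id = subject_id, start_idx = start_idx,
                 end_idx = end_idx, catch_idx = catch_idx,
                 drive_start_idx = drive_start_idx,
                 drive_end_idx = drive_end_idx,
                 stroke_rate_spm = stroke_rate_spm, scalars = scalars),
            class = "rowing_cycle")
}

# slice a channel vector by a cycle's 0-based half-open window
cycle_slice <- function(x, cycle) {
  x[(cycle$start_idx + 1):cycle$end_idx]
}

#' Validate a session's streams against the channel vocabulary
#'
#' Checks that every required channel for the condition is present and that
#' all streams have internally consistent lengths. Boat IMU streams must all
#' share one length (they are interpolated onto a common 100 Hz grid).
#'
#' @param streams named list of [sensor_stream] objects.
#' @param profile a [subject_profile].
#' @return Character vector of human-readable issues; empty when valid.
#' @export
validate_session <- function(streams, profile) {
  req <- .rk_required_channels[[profile$condition]]
  issues <- character(0)
  for (sname in names(req)) {
    if (!sname %in% names(streams)) {
      issues <- c(issues, paste0("missing:", sname))
      next
    }
    st <- streams[[sname]]
    miss <- setdiff(req[[sname]], st$channels)
    if (length(miss)) issues <- c(issues, paste0("missing:", miss))
    if (ncol(st$values) != length(st$channels))
      issues <- c(issues, paste0("length_mismatch:", sname))
  }
  present <- intersect(names(req), names(streams))
  if (length(present) > 1) {
    ns <- vapply(streams[present], function(s) nrow(s$values), integer(1))
    rs <- vapply(streams[present], function(s) s$sample_rate_hz, numeric(1))
    bad <- present[ns != stats::median(ns) | rs != stats::median(rs)]
    if (length(bad)) issues <- c(issues, paste0("length_mismatch:", bad))
  }
  unique(issues)
}

#' Write a session to a directory of CSV files
#'
#' One CSV per stream (first column `time_s`, remaining columns SI-unit
#' channels) plus `subject.json` with the subject metadata, the layout also
#' consumed by [read_session()].
#'
#' @param streams named list of [sensor_stream]s.
#' @param profile a [subject_profile].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(streams, profile, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sname in names(streams)) {
    st <- streams[[sname]]
    df <- data.frame(time_s = stream_time(st), st$values, check.names = FALSE)
    write.csv(df, file.path(dir, paste0(sname, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(
    list(subject_id = profile$subject_id, height_m = profile$height_m,
         mass_kg = profile$mass_kg, condition = profile$condition),
    file.path(dir, "subject.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir session directory.
#' @return List with elements `streams` (named list of [sensor_stream]s) and
#'   `profile` (a [subject_profile]).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "subject.json"), simplifyVector = TRUE)
  profile <- subject_profile(meta$subject_id, meta$height_m, meta$mass_kg,
                             meta$condition)
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "truth.csv"]
  streams <- list()
  for (f in files) {
    df <- read.csv(f, check.names = FALSE)
    tt <- df$time_s
    fs <- 1 / stats::median(diff(tt))
    vals <- as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE])
    streams[[sub("\\.csv$", "", basename(f))]] <-
      sensor_stream(vals, fs, colnames(vals), t0_s = tt[1])
  }
  list(streams = streams, profile = profile)
}
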