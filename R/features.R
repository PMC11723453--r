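# Per-cycle input feature assembly (16 ergometer / 18 boat channels) and
# train-time z-normalization. Feature channels are kinematics-only: no
# measured force or power sequence may enter the input path.

.rk_ergo_features <- c(
  "X_handle", "X_chest", "X_seat",
  "V_handle", "V_arms", "V_trunk", "V_legs",
  "A_handle", "A_trunk", "A_legs",
  "height", "weight",
  "dur_prev_drive", "dur_curr_drive",
  "max_handle_speed_prev", "time_maxspeed_to_catch")

.rk_boat_features <- c(
  "oar_angular_velocity", "V_boat", "A_boat",
  "V_imu_thoracic", "V_imu_lumbar", "V_imu_pelvis",
  "pca_acc_thoracic", "pca_acc_lumbar", "pca_acc_pelvis",
  "pca_gyr_thoracic", "pca_gyr_lumbar", "pca_gyr_pelvis",
  "avg_boat_speed_prev", "max_boat_speed_prev",
  "height", "weight", "dur_prev_drive", "dur_curr_drive")

.rk_target_names <- c("Ff_x", "Fh_x", "Ph_x", "Pa", "Pt", "Pl")

# channels that must never appear among inputs
.rk_forbidden_features <- c(.rk_target_names, "F_handle", "F_feet", "F_feet_x",
                            "Fg_x_port", "Fg_x_starboard", "Fg_y_port",
                            "Fg_y_starboard")

#' First principal component of a 3-axis IMU signal
#'
#' Projects the mean-centered signal onto its first principal axis, fitted
#' over the whole session for one IMU. The sign is fixed so that the
#' loading on the first (forward) axis is positive.
#'
#' @param xyz numeric matrix, `n x 3`.
#' @return Numeric vector of length `n` (the 1PCA channel), with the
#'   explained variance fraction in attribute `"explained"`.
#' @export
first_principal_component <- function(xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3)
  ctr <- scale(xyz, center = TRUE, scale = FALSE)
  sv <- svd(ctr, nu = 0, nv = 3)
  if (sv$d[1] <= 0 || all(sv$d == 0)) stop("degenerate_signal")
  v1 <- sv$v[, 1]
  if (v1[1] < 0) v1 <- -v1
  out <- drop(ctr %*% v1)
  attr(out, "explained") <- sv$d[1]^2 / sum(sv$d^2)
  out
}

# Drive-phase windows and per-cycle scalars for a session. Mutates cycles:
# adds absolute drive indices; returns cycles with scalars attached, cycles
# where no drive was detected are dropped.
annotate_cycles <- function(cycles, handle_force, sample_rate_hz,
                            on_N = 196.2, off_N = 98.1) {
  out <- list()
  for (cy in cycles) {
    seg <- cycle_slice(handle_force, cy)
    dp <- tryCatch(suppressWarnings(detect_drive_phase(seg, on_N, off_N)),
                   error = function(e) NULL)
    if (is.null(dp)) next
    cy$drive_start_idx <- cy$start_idx + dp$drive_start_idx
    cy$drive_end_idx <- cy$start_idx + dp$drive_end_idx
    cy$scalars$drive_dur_s <- (dp$drive_end_idx - dp$drive_start_idx) /
      sample_rate_hz
    out[[length(out) + 1]] <- cy
  }
  out
}

#' Build the 16-channel ergometer feature matrix for one cycle
#'
#' Sequence channels are the three cable positions, the four segment
#' velocities, and the handle/trunk/legs accelerations; scalar descriptors
#' (height, weight, previous/current drive durations, previous-stroke
#' maximum handle speed and its time distance to the current catch) enter
#' as constant channels. The first cycle of a session has no previous-stroke
#' scalars and raises `no_previous_cycle`.
#'
#' @param cycle a drive-annotated [rowing_cycle].
#' @param prev_cycle the preceding cycle (or `NULL`).
#' @param kin session-level `ergo_kinematics` (from
#'   [ergo_segment_kinematics()]).
#' @param profile a [subject_profile].
#' @param sample_rate_hz sampling rate in Hz.
#' @return `cycle_length x 16` feature matrix.
#' @export
build_ergo_features <- function(cycle, prev_cycle, kin, profile,
                                sample_rate_hz) {
  if (is.null(prev_cycle)) stop("no_previous_cycle")
  fs <- sample_rate_hz
  idx <- (cycle$start_idx + 1):cycle$end_idx
  Ah <- differentiate(kin$Vh, fs)
  At <- differentiate(kin$Vt, fs)
  Al <- differentiate(kin$Vl, fs)
  vh_prev <- cycle_slice(kin$Vh, prev_cycle)
  max_vh_prev <- max(vh_prev)
  # time from the previous stroke's handle-speed maximum to the current catch
  i_max <- prev_cycle$start_idx + which.max(vh_prev) - 1
  t_gap <- (cycle$catch_idx - i_max) / fs
  n <- length(idx)
  m <- cbind(
    X_handle = kin$Xh[idx], X_chest = kin$Xc[idx], X_seat = kin$Xs[idx],
    V_handle = kin$Vh[idx], V_arms = kin$Va[idx], V_trunk = kin$Vt[idx],
    V_legs = kin$Vl[idx],
    A_handle = Ah[idx], A_trunk = At[idx], A_legs = Al[idx],
    height = rep(profile$height_m, n), weight = rep(profile$mass_kg, n),
    dur_prev_drive = rep(prev_cycle$scalars$drive_dur_s, n),
    dur_curr_drive = rep(cycle$scalars$drive_dur_s, n),
    max_handle_speed_prev = rep(max_vh_prev, n),
    time_maxspeed_to_catch = rep(t_gap, n))
  stopifnot(identical(colnames(m), .rk_ergo_features))
  m
}

#' Build the 18-channel boat feature matrix for one cycle
#'
#' Sequence channels are the gate angular velocity, boat velocity and
#' acceleration, the three IMU horizontal velocities in the boat frame, and
#' the six session-fitted first-principal-component projections of each
#' IMU's acceleration and angular velocity; scalars (previous-cycle average
#' and maximum boat speed, height, weight, drive durations) are constant
#' channels.
#'
#' @param cycle a drive-annotated [rowing_cycle].
#' @param prev_cycle the preceding cycle (or `NULL`).
#' @param chans named list of session-level channels (see
#'   [prepare_boat_channels()]).
#' @param profile a [subject_profile].
#' @return `cycle_length x 18` feature matrix.
#' @export
build_boat_features <- function(cycle, prev_cycle, chans, profile) {
  if (is.null(prev_cycle)) stop("no_previous_cycle")
  idx <- (cycle$start_idx + 1):cycle$end_idx
  vb_prev <- cycle_slice(chans$V_boat, prev_cycle)
  n <- length(idx)
  m <- cbind(
    oar_angular_velocity = chans$theta_dot[idx],
    V_boat = chans$V_boat[idx], A_boat = chans$A_boat[idx],
    V_imu_thoracic = chans$V_It[idx], V_imu_lumbar = chans$V_Il[idx],
    V_imu_pelvis = chans$V_Ip[idx],
    pca_acc_thoracic = chans$pca_acc_thoracic[idx],
    pca_acc_lumbar = chans$pca_acc_lumbar[idx],
    pca_acc_pelvis = chans$pca_acc_pelvis[idx],
    pca_gyr_thoracic = chans$pca_gyr_thoracic[idx],
    pca_gyr_lumbar = chans$pca_gyr_lumbar[idx],
    pca_gyr_pelvis = chans$pca_gyr_pelvis[idx],
    avg_boat_speed_prev = rep(mean(vb_prev), n),
    max_boat_speed_prev = rep(max(vb_prev), n),
    height = rep(profile$height_m, n), weight = rep(profile$mass_kg, n),
    dur_prev_drive = rep(prev_cycle$scalars$drive_dur_s, n),
    dur_curr_drive = rep(cycle$scalars$drive_dur_s, n))
  stopifnot(identical(colnames(m), .rk_boat_features))
  m
}

#' Session-level boat channels feeding the feature builder
#'
#' Computes the starboard gate angular velocity, IMU horizontal velocities
#' (drift-removed integration of forward free acceleration), and the
#' session-fitted 1PCA projections of each body IMU.
#'
#' @param streams named list of preprocessed boat [sensor_stream]s.
#' @param smooth_hz optional differentiation smoothing cutoff, Hz.
#' @return Named list of session-length channels.
#' @export
prepare_boat_channels <- function(streams, smooth_hz = NULL) {
  fs <- streams$oars$sample_rate_hz
  out <- list(
    theta_dot = differentiate(stream_channel(streams$oars, "theta_starboard"),
                              fs, smooth_hz),
    V_boat = stream_channel(streams$gps, "V_boat"),
    A_boat = stream_channel(streams$boat_imu, "A_boat"),
    V_It = integrate_and_highpass(stream_channel(streams$imu_thoracic, "acc_x"), fs),
    V_Il = integrate_and_highpass(stream_channel(streams$imu_lumbar, "acc_x"), fs),
    V_Ip = integrate_and_highpass(stream_channel(streams$imu_pelvis, "acc_x"), fs))
  for (imu in c("thoracic", "lumbar", "pelvis")) {
    st <- streams[[paste0("imu_", imu)]]
    out[[paste0("pca_acc_", imu)]] <-
      first_principal_component(st$values[, c("acc_x", "acc_y", "acc_z")])
    out[[paste0("pca_gyr_", imu)]] <-
      first_principal_component(st$values[, c("gyr_x", "gyr_y", "gyr_z")])
  }
  out
}

#' Fit per-channel normalization statistics on training cycles
#'
#' Means and standard deviations are pooled over all samples of the
#' training cycles, for input features and targets alike; application is
#' `z = (x - mean) / sd`. Channels with zero spread get `sd = 1` with a
#' warning.
#'
#' @param mats list of numeric matrices (`length x channels`), training
#'   cycles only.
#' @return Object of class `norm_stats` with `mean` and `sd` per channel.
#' @export
fit_norm <- function(mats) {
  stopifnot(length(mats) >= 2)
  pooled <- do.call(rbind, mats)
  mu <- colMeans(pooled)
  s <- apply(pooled, 2, sd)
  zero <- !is.finite(s) | s == 0
  if (any(zero)) {
    warning("zero-spread channel(s): ", paste(names(mu)[zero], collapse = ", "))
    s[zero] <- 1
  }
  structure(list(mean = mu, sd = s), class = "norm_stats")
}

#' Apply z-normalization
#' @param m numeric matrix (`length x channels`).
#' @param ns a `norm_stats` object.
#' @return Normalized matrix.
#' @export
apply_norm <- function(m, ns) sweep(sweep(m, 2, ns$mean), 2, ns$sd, "/")

#' Invert z-normalization back to original units
#' @param m normalized matrix.
#' @param ns a `norm_stats` object.
#' @return De-normalized matrix.
#' @export
invert_norm <- function(m, ns) sweep(sweep(m, 2, ns$sd, "*"), 2, ns$mean, "+")

assert_no_force_features <- function(channel_names) {
  bad <- intersect(channel_names, .rk_forbidden_features)
  if (length(bad))
    stop("measured force/power channel(s) in the feature path: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
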