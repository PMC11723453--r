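# Kinetic target computation: handle/gate power and the arms/trunk/legs
# power decomposition, for ergometer and scull-boat rowing.

#' Ergometer segment kinematics from the three cable positions
#'
#' Arm length is the handle-to-chest distance `Xa = Xh - Xc`; trunk opening
#' is chest-to-seat `Xt = Xc - Xs`; leg extension is taken as the seat
#' position itself. Velocities are time derivatives (central differences,
#' optionally smoothed).
#'
#' @param Xh,Xc,Xs handle, chest, seat positions in m (equal length).
#' @param sample_rate_hz sampling rate in Hz.
#' @param smooth_hz optional low-pass cutoff passed to [differentiate()].
#' @return List of class `ergo_kinematics` with positions `Xh, Xc, Xs, Xa,
#'   Xt` and velocities `Vh, Va, Vt, Vl`.
#' @export
ergo_segment_kinematics <- function(Xh, Xc, Xs, sample_rate_hz,
                                    smooth_hz = NULL) {
  stopifnot(length(Xh) == length(Xc), length(Xc) == length(Xs))
  Xa <- Xh - Xc
  Xt <- Xc - Xs
  structure(list(
    Xh = Xh, Xc = Xc, Xs = Xs, Xa = Xa, Xt = Xt,
    Vh = differentiate(Xh, sample_rate_hz, smooth_hz),
    Va = differentiate(Xa, sample_rate_hz, smooth_hz),
    Vt = differentiate(Xt, sample_rate_hz, smooth_hz),
    Vl = differentiate(Xs, sample_rate_hz, smooth_hz)), class = "ergo_kinematics")
}

#' Ergometer handle and segment powers
#'
#' `Ph_x = Vh * Fh_x`, `Pa = Va * Fh_x`, `Pt = Vt * Fh_x`, `Pl = Vl * Ff_x`
#' samplewise; the handle force (chain tension) loads arms and trunk, the
#' foot-stretcher force loads the legs.
#'
#' @param kin an `ergo_kinematics` object.
#' @param Fh_x handle (chain) force in N.
#' @param Ff_x horizontal foot-stretcher force in N.
#' @return List with `Ph_x`, `Pa`, `Pt`, `Pl` in W.
#' @export
ergo_powers <- function(kin, Fh_x, Ff_x) {
  if (length(Fh_x) != length(kin$Vh) || length(Ff_x) != length(kin$Vh))
    stop("force/kinematics length mismatch")
  list(Ph_x = kin$Vh * Fh_x, Pa = kin$Va * Fh_x,
       Pt = kin$Vt * Fh_x, Pl = kin$Vl * Ff_x)
}

#' Power transferred to the oars at the gates
#'
#' Per side, `Ph = (Fh_x * li * cos(theta) + Fh_y * li * sin(theta)) *
#' theta_dot`; the total is the sum of the port and starboard sides, with
#' the x/y components also returned separately.
#'
#' @param theta list with `port` and `starboard` oar angles in rad.
#' @param theta_dot list with per-side angular velocities in rad/s.
#' @param Fh_x,Fh_y lists with per-side gate force components in N.
#' @param li inner lever (gate-to-handle) length in m.
#' @return List with `Ph`, `Ph_x`, `Ph_y` (port+starboard sums, W).
#' @export
boat_handle_power <- function(theta, theta_dot, Fh_x, Fh_y, li = 0.88) {
  sides <- c("port", "starboard")
  Px <- Py <- 0
  for (s in sides) {
    Px <- Px + Fh_x[[s]] * li * cos(theta[[s]]) * theta_dot[[s]]
    Py <- Py + Fh_y[[s]] * li * sin(theta[[s]]) * theta_dot[[s]]
  }
  list(Ph = Px + Py, Ph_x = Px, Ph_y = Py)
}

#' Trunk and leg velocities from the body-worn IMUs
#'
#' Trunk velocity is the thoracic-minus-pelvis IMU horizontal velocity
#' (both expressed in the boat frame); leg velocity corrects the pelvis IMU
#' velocity for the rotation of the pelvis about the seat:
#' `Vl = V_Ip - l_Ip * theta_dot_Ip * cos(theta_Ip)`.
#'
#' @param V_It,V_Ip thoracic and pelvis IMU horizontal velocities, m/s.
#' @param theta_Ip pelvis tilt from vertical, rad.
#' @param theta_dot_Ip pelvis tilt angular velocity, rad/s.
#' @param l_Ip pelvis-IMU-to-seat distance in m (0.15 m for all subjects).
#' @return List with `Vt` and `Vl` in m/s.
#' @export
boat_segment_velocities <- function(V_It, V_Ip, theta_Ip, theta_dot_Ip,
                                    l_Ip = 0.15) {
  stopifnot(l_Ip > 0)
  list(Vt = V_It - V_Ip,
       Vl = V_Ip - l_Ip * theta_dot_Ip * cos(theta_Ip))
}

#' Trunk and leg powers on the boat
#'
#' `Pl = Ff_x * Vl` and `Pt = Fh_x_sum * Vt`, where `Fh_x_sum` is the
#' port+starboard propulsive gate force.
#'
#' @param Ff_x horizontal foot-stretcher force, N.
#' @param Fh_x_sum summed propulsive gate force, N.
#' @param Vt,Vl trunk and leg velocities, m/s.
#' @return List with `Pt` and `Pl` in W.
#' @export
boat_segment_powers <- function(Ff_x, Fh_x_sum, Vt, Vl) {
  list(Pt = Fh_x_sum * Vt, Pl = Ff_x * Vl)
}

#' Arm power on the boat by closure of the power balance
#'
#' The total power produced by the rower is the power at the oars plus the
#' power spent accelerating the body relative to the boat; with a
#' three-segment rower model this leaves
#' `Pa = Ph + (Ff_x - Fh_x_sum) * V_boat - Pt - Pl`.
#'
#' @param Ph total oar power, W.
#' @param Ff_x horizontal foot-stretcher force, N.
#' @param Fh_x_sum summed propulsive gate force, N.
#' @param V_boat boat velocity (GPS), m/s.
#' @param Pt,Pl trunk and leg powers, W.
#' @return Arm power `Pa` in W.
#' @export
boat_arm_power <- function(Ph, Ff_x, Fh_x_sum, V_boat, Pt, Pl) {
  Ph + (Ff_x - Fh_x_sum) * V_boat - Pt - Pl
}

# Session-level target channels (full length); cycles slice into these.
session_target_channels <- function(streams, condition, li = 0.88,
                                    smooth_hz = NULL) {
  if (condition == "ergometer") {
    st <- streams$sensors
    fs <- st$sample_rate_hz
    kin <- ergo_segment_kinematics(stream_channel(st, "X_handle"),
                                   stream_channel(st, "X_chest"),
                                   stream_channel(st, "X_seat"), fs, smooth_hz)
    Fh <- stream_channel(st, "F_handle")
    Ff <- stream_channel(st, "F_feet")
    pw <- ergo_powers(kin, Fh, Ff)
    list(Ff_x = Ff, Fh_x = Fh, Ph_x = pw$Ph_x, Pa = pw$Pa, Pt = pw$Pt,
         Pl = pw$Pl)
  } else {
    oars <- streams$oars
    fs <- oars$sample_rate_hz
    theta <- list(port = stream_channel(oars, "theta_port"),
                  starboard = stream_channel(oars, "theta_starboard"))
    theta_dot <- lapply(theta, differentiate, sample_rate_hz = fs,
                        smooth_hz = smooth_hz)
    Fgx <- list(port = stream_channel(oars, "Fg_x_port"),
                starboard = stream_channel(oars, "Fg_x_starboard"))
    Fgy <- list(port = stream_channel(oars, "Fg_y_port"),
                starboard = stream_channel(oars, "Fg_y_starboard"))
    hp <- boat_handle_power(theta, theta_dot, Fgx, Fgy, li = li)
    Fh_sum <- Fgx$port + Fgx$starboard
    Ff <- stream_channel(streams$stretcher, "F_feet_x")
    V_boat <- stream_channel(streams$gps, "V_boat")
    V_Ip <- integrate_and_highpass(stream_channel(streams$imu_pelvis, "acc_x"), fs)
    V_It <- integrate_and_highpass(stream_channel(streams$imu_thoracic, "acc_x"), fs)
    tilt <- stream_channel(streams$imu_pelvis, "tilt")
    tilt_dot <- stream_channel(streams$imu_pelvis, "gyr_x")
    sv <- boat_segment_velocities(V_It, V_Ip, tilt, tilt_dot)
    sp <- boat_segment_powers(Ff, Fh_sum, sv$Vt, sv$Vl)
    Pa <- boat_arm_power(hp$Ph, Ff, Fh_sum, V_boat, sp$Pt, sp$Pl)
    list(Ff_x = Ff, Fh_x = Fh_sum, Ph_x = hp$Ph, Pa = Pa, Pt = sp$Pt,
         Pl = sp$Pl)
  }
}

#' Assemble the six kinetic target sequences per cycle
#'
#' Targets are `Ff_x`, `Fh_x`, `Ph_x`, `Pa`, `Pt`, `Pl`. On the ergometer
#' `Fh_x` is the measured chain tension and `Ph_x` the handle power; on the
#' boat `Fh_x` is the port+starboard propulsive gate-force sum and `Ph_x`
#' the total oar power. Cycles that extend past the stream end are dropped.
#'
#' @param streams named list of preprocessed [sensor_stream]s.
#' @param cycles list of [rowing_cycle]s from [segment_cycles()].
#' @param condition `"ergometer"` or `"boat"`.
#' @param li inner lever length in m (boat only).
#' @param smooth_hz optional differentiation smoothing cutoff.
#' @return List (one element per retained cycle) of lists with the six
#'   equal-length target sequences plus the originating `cycle`.
#' @export
build_targets <- function(streams, cycles, condition, li = 0.88,
                          smooth_hz = NULL) {
  chans <- session_target_channels(streams, condition, li, smooth_hz)
  n <- length(chans$Ff_x)
  out <- list()
  for (cy in cycles) {
    if (cy$end_idx > n) next
    tg <- lapply(chans, cycle_slice, cycle = cy)
    tg$cycle <- cy
    out[[length(out) + 1]] <- tg
  }
  out
}
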