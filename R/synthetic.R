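# Synthetic rowing-session generator. Phenomenological forward model of
# cyclic rowing: smooth monotone segment excursions staggered legs -> trunk
# -> arms within the drive, a skewed raised-cosine force pulse with
# controllable peak position, and forces tied to the kinematics (peak force
# scales with cycle speed and excursion) so that kinematic inputs carry
# force information. Ground-truth targets are computed from the noise-free
# channels through the kinetics module, so truth is exactly self-consistent
# with target recomputation.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Construct a set of subject technique parameters
#'
#' @param stroke_rate_spm strokes per minute.
#' @param drive_fraction fraction of the cycle spent in the drive, (0.25, 0.6).
#' @param peak_force_N nominal peak handle/gate force, N.
#' @param force_peak_position fraction of the drive at which force peaks, (0,1).
#' @param segment_phase_offsets numeric length-3 (legs, trunk, arms) drive
#'   onset fractions, strictly increasing, each in [0, 0.45].
#' @param seg_duration_frac fraction of the drive over which the legs and
#'   trunk complete their excursion, in (0.4, 0.65).
#' @param force_sharpness exponent applied to the force pulse; > 1 gives a
#'   peakier pull (lower M2P), < 1 a flatter one.
#' @param foot_peak_lag how much earlier (fraction of drive) the
#'   foot-stretcher force peaks relative to the handle/gate force.
#' @param foot_amp_ratio peak foot force relative to peak handle force.
#' @param seg_skew numeric length-3 (legs, trunk, arms) time-warp exponents
#'   in (0.7, 1.4) skewing each segment's drive velocity profile early
#'   (< 1) or late (> 1); rower-specific movement style.
#' @param arm_negative_power_flag reproduce the early-arm-peak technical
#'   fault that yields a negative arm-power segment within the drive.
#' @param noise_sd multiplier on the per-channel measurement-noise scales.
#' @param seed integer seed driving all session randomness.
#' @return An object of class `technique_params`.
#' @export
technique_params <- function(stroke_rate_spm = 35, drive_fraction = 0.4,
                             peak_force_N = 750, force_peak_position = 0.4,
                             segment_phase_offsets = c(0, 0.2, 0.4),
                             seg_duration_frac = 0.55, force_sharpness = 1,
                             foot_peak_lag = 0.12, foot_amp_ratio = 1.12,
                             seg_skew = c(1, 1, 1),
                             arm_negative_power_flag = FALSE,
                             noise_sd = 1, seed = 1) {
  stopifnot(drive_fraction > 0.25, drive_fraction < 0.6,
            force_peak_position > 0, force_peak_position < 1,
            length(segment_phase_offsets) == 3,
            all(diff(segment_phase_offsets) > 0),
            all(segment_phase_offsets >= 0), all(segment_phase_offsets <= 0.45),
            seg_duration_frac > 0.4, seg_duration_frac < 0.65,
            force_sharpness > 0.5, force_sharpness < 2,
            foot_peak_lag >= 0, foot_peak_lag < 0.3,
            foot_amp_ratio > 0.8, foot_amp_ratio < 1.5,
            length(seg_skew) == 3, all(seg_skew > 0.7), all(seg_skew < 1.4))
  structure(list(stroke_rate_spm = stroke_rate_spm,
                 drive_fraction = drive_fraction,
                 peak_force_N = peak_force_N,
                 force_peak_position = force_peak_position,
                 segment_phase_offsets = segment_phase_offsets,
                 seg_duration_frac = seg_duration_frac,
                 force_sharpness = force_sharpness,
                 foot_peak_lag = foot_peak_lag,
                 foot_amp_ratio = foot_amp_ratio,
                 seg_skew = seg_skew,
                 arm_negative_power_flag = arm_negative_power_flag,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "technique_params")
}

# cohort statistics used by the subject sampler (mean, sd)
.rk_cohort <- list(
  ergometer = list(height = c(1.855, 0.071), mass = c(77.4, 7.0),
                   spm = c(35.8, 1.8)),
  boat = list(height = c(1.85, 0.05), mass = c(79.0, 6.7),
              spm = c(32.5, 1.5))
)

#' Draw a subject profile and technique parameters
#'
#' Heights and masses are drawn near the cohort statistics of the modelled
#' populations; technique parameters are drawn with inter-subject spread
#' (peak position, phase offsets, drive fraction) well above the
#' within-subject cycle jitter, so that technique determinants separate
#' subjects.
#'
#' @param condition `"ergometer"` or `"boat"`.
#' @param seed integer seed; identical seeds give identical draws.
#' @return List with `profile` ([subject_profile]) and `params`
#'   ([technique_params]).
#' @export
sample_subject <- function(condition, seed) {
  condition <- match.arg(condition, c("ergometer", "boat"))
  co <- .rk_cohort[[condition]]
  with_seed(seed, {
    height <- min(2.2, max(1.55, rnorm(1, co$height[1], co$height[2])))
    mass <- min(120, max(50, rnorm(1, co$mass[1], co$mass[2])))
    spm <- max(16, rnorm(1, co$spm[1], co$spm[2]))
    offs <- c(0, runif(1, 0.15, 0.25), runif(1, 0.35, 0.45))
    params <- technique_params(
      stroke_rate_spm = spm,
      drive_fraction = runif(1, 0.35, 0.45),
      peak_force_N = rnorm(1, 750, 80) * (mass / co$mass[1]),
      force_peak_position = runif(1, 0.3, 0.5),
      segment_phase_offsets = offs,
      seg_duration_frac = runif(1, 0.45, 0.62),
      force_sharpness = runif(1, 0.8, 1.3),
      foot_peak_lag = runif(1, 0.08, 0.16),
      foot_amp_ratio = runif(1, 1.05, 1.2),
      seg_skew = runif(3, 0.75, 1.35),
      arm_negative_power_flag = runif(1) < 0.25,
      noise_sd = 1, seed = seed)
    list(profile = subject_profile(paste0("S", seed), height, mass, condition),
         params = params)
  })
}

# smooth monotone 0->1 step
rc_step <- function(w) 0.5 * (1 - cos(pi * pmin(pmax(w, 0), 1)))

# 0->1->0 pulse over w in [0,1], peak exactly at w = p
force_pulse <- function(w, p) {
  w <- pmin(pmax(w, 0), 1)
  ifelse(w <= p, 0.5 * (1 - cos(pi * w / p)),
         0.5 * (1 + cos(pi * (w - p) / (1 - p))))
}

# window w through [a, b], clamped
wf <- function(w, a, b) pmin(pmax((w - a) / (b - a), 0), 1)

# Segment drive/recovery windows: legs move first in the drive, arms first
# in the recovery. Legs start exactly at the catch and arms finish exactly
# at the finish (and mirrored in the recovery), so the summed handle
# position has strict extrema at the stroke events rather than plateaus.
seg_windows <- function(offsets, dur = 0.55) {
  list(drive = list(legs = c(offsets[1], offsets[1] + dur),
                    trunk = c(offsets[2], min(1, offsets[2] + dur)),
                    arms = c(offsets[3], 1.0)),
       recovery = list(arms = c(0, 0.55), trunk = c(0.225, 0.775),
                       legs = c(0.45, 1.0)))
}

# normalized (0..1) excursion of one segment at cycle phase u; the drive
# profile is time-warped by the subject's per-segment skew exponent
seg_excursion <- function(u, seg, par) {
  win <- seg_windows(par$segment_phase_offsets, par$seg_duration_frac)
  rho <- par$drive_fraction
  skew <- par$seg_skew[match(seg, c("legs", "trunk", "arms"))]
  if (is.na(skew)) skew <- 1
  rec <- u < (1 - rho)
  out <- numeric(length(u))
  wr <- wf(u[rec] / (1 - rho), win$recovery[[seg]][1], win$recovery[[seg]][2])
  out[rec] <- 1 - rc_step(wr)
  wd <- wf((u[!rec] - (1 - rho)) / rho, win$drive[[seg]][1], win$drive[[seg]][2])
  # quadratic time warp: monotone, endpoint-preserving, bounded curvature
  lam <- 2 * (skew - 1)
  out[!rec] <- rc_step((1 - lam) * wd + lam * wd^2)
  out
}

drive_w <- function(u, rho) ifelse(u >= 1 - rho, (u - (1 - rho)) / rho, NA_real_)

# Per-cycle phase/amplitude bookkeeping shared by both simulators.
# Returns phase vector u, cycle amplitude factor per sample (previous/current
# for positions; current for forces), and force amplitude factor per sample.
session_phases <- function(params, n_cycles, fs) {
  Tnom <- 60 / params$stroke_rate_spm
  dur_jit <- 1 + runif(n_cycles, -0.03, 0.03)
  amp_jit <- 1 + runif(n_cycles, -0.05, 0.05)
  Tc <- Tnom * dur_jit
  nk <- pmax(4, round(Tc * fs))
  pad_pre <- max(3, round(0.35 * params$drive_fraction * Tnom * fs))
  pad_post <- max(3, round(0.35 * (1 - params$drive_fraction) * Tnom * fs))
  u <- c(1 - (pad_pre:1) / nk[1],                       # tail of a lead-in drive
         unlist(lapply(nk, function(n) (0:(n - 1)) / n)),
         (0:(pad_post - 1)) / nk[n_cycles])             # start of a trailing recovery
  cyc_id <- c(rep(0L, pad_pre), rep(seq_len(n_cycles), nk),
              rep(n_cycles + 1L, pad_post))
  amp <- c(amp_jit[1], amp_jit, amp_jit[n_cycles])      # amp of cycle c = amp[c + 1]
  ampP <- amp[pmax(1, cyc_id)]                          # amplitude of previous drive
  ampC <- amp[cyc_id + 1]                               # amplitude of current drive
  # force amplitude couples to cycle speed: shorter, larger cycles are faster
  spd <- amp_jit * Tnom / Tc
  spd_all <- c(spd[1], spd, spd[n_cycles])
  famp <- spd_all[cyc_id + 1]
  list(u = u, ampP = ampP, ampC = ampC, famp = famp, n = length(u), nk = nk)
}

#' Simulate an ergometer rowing session
#'
#' Emits cable-sensor position streams (handle, chest, seat) and the
#' handle/foot force streams at 150 Hz, together with noise-free
#' ground-truth targets computed through the kinetics equations. Handle
#' force is zero throughout the recovery (measurement noise is clipped at
#' zero: the chain only carries tension) and rises smoothly during the
#' drive, peaking at `force_peak_position` of the drive.
#'
#' @param profile a [subject_profile].
#' @param params a [technique_params].
#' @param n_cycles number of complete finish-to-finish cycles (>= 1).
#' @param sample_rate_hz sampling rate, Hz.
#' @return List with `streams` (named list of [sensor_stream]s, measurement
#'   noise included), `truth` (the six noise-free target channels over the
#'   whole session), `profile`, `params`.
#' @export
simulate_ergo_session <- function(profile, params, n_cycles,
                                  sample_rate_hz = 150) {
  stopifnot(n_cycles >= 1)
  with_seed(params$seed, {
    ph <- session_phases(params, n_cycles, sample_rate_hz)
    hsc <- profile$height_m / 1.85
    rng <- list(legs = 0.52 * hsc, trunk = 0.22 * hsc, arms = 0.45 * hsc)
    rho <- params$drive_fraction
    pos <- list()
    for (seg in c("legs", "trunk", "arms")) {
      ex <- seg_excursion(ph$u, seg, params)
      amp <- ifelse(ph$u < (1 - rho), ph$ampP, ph$ampC) * rng[[seg]]
      pos[[seg]] <- ex * amp
    }
    if (params$arm_negative_power_flag) {
      wd <- drive_w(ph$u, rho)
      dip <- 0.06 * hsc * sin(pi * wf(ifelse(is.na(wd), 0, wd), 0.22, 0.55))^2
      pos$arms <- pos$arms - ifelse(is.na(wd), 0, dip)
    }
    Xs <- 0.05 + pos$legs
    Xc <- 0.35 * hsc + Xs + pos$trunk
    Xh <- 0.45 * hsc + Xc + pos$arms
    wd <- drive_w(ph$u, rho)
    A <- params$peak_force_N * ph$famp
    p <- params$force_peak_position
    q <- params$force_sharpness
    pf <- max(0.15, p - params$foot_peak_lag)
    wds <- ifelse(is.na(wd), 0, wd)
    Fh <- ifelse(is.na(wd), 0, A * force_pulse(wds, p)^q)
    Ff <- ifelse(is.na(wd), 0,
                 params$foot_amp_ratio * A * force_pulse(wds, pf)^q)
    clean <- cbind(X_handle = Xh, X_chest = Xc, X_seat = Xs,
                   F_handle = Fh, F_feet = Ff)
    truth_streams <- list(sensors = sensor_stream(clean, sample_rate_hz,
                                                  colnames(clean)))
    truth <- session_target_channels(truth_streams, "ergometer")
    ns <- params$noise_sd
    noisy <- clean
    noisy[, 1:3] <- noisy[, 1:3] + rnorm(3 * ph$n, 0, 0.0005 * ns)
    noisy[, 4] <- pmax(0, noisy[, 4] + rnorm(ph$n, 0, 2 * ns))
    noisy[, 5] <- pmax(0, noisy[, 5] + rnorm(ph$n, 0, 2 * ns))
    if (ns == 0) noisy <- clean
    streams <- list(sensors = sensor_stream(noisy, sample_rate_hz,
                                            colnames(clean)))
    list(streams = streams, truth = truth, profile = profile, params = params)
  })
}

#' Simulate a scull-boat rowing session
#'
#' Emits, at 100 Hz: port/starboard oar angles and gate force components,
#' horizontal foot-stretcher force, GPS-like boat velocity (optionally with
#' a constant clock offset against the IMU streams, for synchronization
#' testing), boat accelerometer, and three body-worn IMU streams (pelvis,
#' lumbar, thoracic: forward free acceleration, angular velocity, and the
#' pelvis tilt). Oar-angle minima mark the catches. Ground-truth targets are
#' computed from the noise-free channels through the kinetics equations
#' (with the same drift-removed integration used for recomputation).
#'
#' @param profile a [subject_profile].
#' @param params a [technique_params].
#' @param n_cycles number of complete cycles (>= 1).
#' @param sample_rate_hz sampling rate, Hz.
#' @param gps_offset_s constant time offset of the GPS clock relative to the
#'   IMU clock, seconds (0 = synchronized).
#' @param li inner lever length in m.
#' @return As [simulate_ergo_session()].
#' @export
simulate_boat_session <- function(profile, params, n_cycles,
                                  sample_rate_hz = 100, gps_offset_s = 0,
                                  li = 0.88) {
  stopifnot(n_cycles >= 1)
  fs <- sample_rate_hz
  with_seed(params$seed, {
    ph <- session_phases(params, n_cycles, fs)
    rho <- params$drive_fraction
    tt <- (seq_len(ph$n) - 1) / fs
    hsc <- profile$height_m / 1.85
    # oar angle: min (catch) to max (finish) over the drive, back in recovery
    th_min <- -0.95; th_max <- 0.55
    sweep <- ifelse(ph$u < (1 - rho), 1 - rc_step(ph$u / (1 - rho)),
                    rc_step((ph$u - (1 - rho)) / rho))
    theta_sb <- th_min + (th_max - th_min) * sweep
    theta_pt <- theta_sb
    wd <- drive_w(ph$u, rho)
    wds <- ifelse(is.na(wd), 0, wd)
    A <- params$peak_force_N * ph$famp
    p <- params$force_peak_position
    q <- params$force_sharpness
    pf <- max(0.15, p - params$foot_peak_lag)
    Fg_x <- ifelse(is.na(wd), 0, 0.5 * A * force_pulse(wds, p)^q)
    Fg_y <- 0.3 * Fg_x
    Ff <- ifelse(is.na(wd), 0,
                 params$foot_amp_ratio * A * force_pulse(wds, pf)^q)
    # body segment excursions w.r.t. the boat
    exl <- seg_excursion(ph$u, "legs", params)
    ext <- seg_excursion(ph$u, "trunk", params)
    ampl <- ifelse(ph$u < (1 - rho), ph$ampP, ph$ampC)
    p_pel <- 0.55 * hsc * exl * ampl
    p_tho <- p_pel + 0.25 * hsc * ext * ampl
    p_lum <- p_pel + 0.125 * hsc * ext * ampl
    V_pel <- differentiate(p_pel, fs)
    V_tho <- differentiate(p_tho, fs)
    V_lum <- differentiate(p_lum, fs)
    tilt <- -0.35 + 0.75 * ext
    gyr_x_pel <- differentiate(tilt, fs)
    # boat speed: slowest around the catch, fastest late in the drive, plus
    # a slow non-periodic meander (effort/wind/water) that real GPS records
    # and that makes velocity-based synchronization well-posed. The GPS log
    # outlasts the IMU window, so the velocity record is generated with a
    # margin on both sides and the planted clock offset samples from it.
    V0 <- 4.5 * (1 + 0.1 * (hsc - 1))
    dv <- 0.45
    mar <- round(3 * fs)
    u_ext <- c((ph$u[1] - (mar:1) / ph$nk[1]) %% 1, ph$u,
               (ph$u[ph$n] + (1:mar) / ph$nk[length(ph$nk)]) %% 1)
    meander <- lowpass(rnorm(length(u_ext)), fs, 0.5)
    meander <- 0.2 * meander / max(sd(meander), 1e-12)
    famp_ext <- c(rep(ph$famp[1], mar), ph$famp, rep(ph$famp[ph$n], mar))
    V_ext <- V0 - dv * famp_ext * cos(2 * pi * (u_ext - (1 - rho))) + meander
    V_boat <- V_ext[(mar + 1):(mar + ph$n)]
    A_boat <- differentiate(V_boat, fs)
    mk_imu <- function(V_seg, gxr) {
      acc_x <- differentiate(V_seg, fs)
      cbind(acc_x = acc_x,
            acc_y = 0.3 * sin(2 * pi * ph$u) * hsc,
            acc_z = 0.15 * cos(2 * pi * ph$u),
            gyr_x = gxr,
            gyr_y = 0.05 * sin(2 * pi * ph$u + 1),
            gyr_z = 0.05 * cos(2 * pi * ph$u + 2))
    }
    pel <- cbind(mk_imu(V_pel, gyr_x_pel), tilt = tilt)
    lum <- mk_imu(V_lum, 0.8 * gyr_x_pel)
    tho <- mk_imu(V_tho, 0.6 * gyr_x_pel)
    clean <- list(
      oars = cbind(theta_port = theta_pt, theta_starboard = theta_sb,
                   Fg_x_port = Fg_x, Fg_x_starboard = Fg_x,
                   Fg_y_port = Fg_y, Fg_y_starboard = Fg_y),
      stretcher = cbind(F_feet_x = Ff),
      gps = cbind(V_boat = V_boat),
      boat_imu = cbind(A_boat = A_boat),
      imu_pelvis = pel, imu_lumbar = lum, imu_thoracic = tho)
    truth_streams <- lapply(clean, function(m)
      sensor_stream(m, fs, colnames(m)))
    truth <- session_target_channels(truth_streams, "boat", li = li)
    ns <- params$noise_sd
    sdmap <- list(oars = c(0.005, 0.005, 3, 3, 1.5, 1.5), stretcher = 3,
                  gps = 0.05, boat_imu = 0.05,
                  imu_pelvis = c(0.05, 0.05, 0.05, 0.01, 0.01, 0.01, 0.005),
                  imu_lumbar = rep(c(0.05, 0.01), c(3, 3)),
                  imu_thoracic = rep(c(0.05, 0.01), c(3, 3)))
    noisy <- clean
    if (ns > 0) {
      for (sname in names(noisy)) {
        m <- noisy[[sname]]
        for (j in seq_len(ncol(m)))
          m[, j] <- m[, j] + rnorm(nrow(m), 0, sdmap[[sname]][j] * ns)
        # forces cannot be negative pulls during recovery; clip at zero
        fcols <- grep("^F", colnames(m))
        for (j in fcols) m[, j] <- pmax(0, m[, j])
        noisy[[sname]] <- m
      }
    }
    if (abs(gps_offset_s) > 0) {
      t_ext <- (seq(-mar, ph$n - 1 + mar)) / fs
      vshift <- approx(t_ext, V_ext, xout = tt - gps_offset_s, rule = 2)$y
      noisy$gps[, 1] <- vshift + rnorm(ph$n, 0, 0.05 * ns)
    }
    streams <- lapply(noisy, function(m) sensor_stream(m, fs, colnames(m)))
    list(streams = streams, truth = truth, profile = profile, params = params)
  })
}
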