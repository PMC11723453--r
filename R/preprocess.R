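# Stream preprocessing: drift-removed integration, synchronization,
# resampling, differentiation, cycle segmentation, drive-phase detection.

# Zero-phase Butterworth with mirror padding to suppress edge transients.
filtfilt_padded <- function(b_a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(b_a, xp)
  y[(pad + 1):(pad + n)]
}

#' Integrate acceleration to velocity with drift removal
#'
#' Cumulative trapezoidal integration followed by a zero-phase 2nd-order
#' Butterworth high-pass at `cutoff_hz` (default 0.1 Hz) to remove the
#' low-frequency drift that accumulates in integrated accelerometer data.
#' The output is approximately zero-mean.
#'
#' @param accel numeric vector, acceleration in m/s^2, uniformly sampled.
#' @param sample_rate_hz sampling rate in Hz.
#' @param cutoff_hz high-pass cutoff in Hz.
#' @return Velocity vector in m/s, same length as `accel`.
#' @export
integrate_and_highpass <- function(accel, sample_rate_hz, cutoff_hz = 0.1) {
  settle_s <- 1 / (2 * pi * cutoff_hz)  # dominant time constant of the filter
  if (length(accel) < 3 * settle_s * sample_rate_hz) stop("too_short")
  v <- pracma::cumtrapz(seq_along(accel) / sample_rate_hz, accel)[, 1]
  highpass(v, sample_rate_hz, cutoff_hz)
}

#' Zero-phase high-pass filter
#'
#' @param x numeric vector.
#' @param sample_rate_hz sampling rate in Hz.
#' @param cutoff_hz cutoff frequency in Hz.
#' @return Filtered vector.
#' @export
highpass <- function(x, sample_rate_hz, cutoff_hz = 0.1) {
  bf <- signal::butter(2, cutoff_hz / (sample_rate_hz / 2), type = "high")
  filtfilt_padded(bf, x, pad = round(2 * sample_rate_hz / cutoff_hz))
}

lowpass <- function(x, sample_rate_hz, cutoff_hz) {
  bf <- signal::butter(2, cutoff_hz / (sample_rate_hz / 2), type = "low")
  filtfilt_padded(bf, x, pad = round(min(length(x) - 1, 2 * sample_rate_hz / cutoff_hz)))
}

#' Synchronize two velocity channels by cross-correlation
#'
#' Finds the lag (applied to `imu_velocity`) that maximizes the normalized
#' cross-correlation with `gps_velocity` within `max_lag_s`. Both inputs
#' must already be identically high-pass filtered and resampled onto a
#' common rate.
#'
#' @param gps_velocity,imu_velocity numeric vectors at `sample_rate_hz`.
#' @param sample_rate_hz common sampling rate in Hz.
#' @param max_lag_s maximum |lag| searched, seconds.
#' @param min_correlation peak correlation below which sync is rejected.
#' @return List of class `sync_result`: `lag_s` (time shift to add to the
#'   IMU stream clock to align it with GPS) and `correlation` at that lag.
#' @export
synchronize <- function(gps_velocity, imu_velocity, sample_rate_hz,
                        max_lag_s = 5, min_correlation = 0.5) {
  max_lag <- round(max_lag_s * sample_rate_hz)
  lags <- -max_lag:max_lag
  n <- min(length(gps_velocity), length(imu_velocity))
  g <- gps_velocity[seq_len(n)]
  m <- imu_velocity[seq_len(n)]
  cc <- vapply(lags, function(L) {
    # positive lag: IMU events happen earlier on its own clock; shift right
    if (L >= 0) {
      a <- g[(1 + L):n]; b <- m[1:(n - L)]
    } else {
      a <- g[1:(n + L)]; b <- m[(1 - L):n]
    }
    if (length(a) < 10 || sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, numeric(1))
  k <- which.max(cc)
  if (!is.finite(cc[k]) || cc[k] < min_correlation) stop("sync_failed")
  structure(list(lag_s = lags[k] / sample_rate_hz, correlation = cc[k]),
            class = "sync_result")
}

#' Resample a sensor stream by linear interpolation
#'
#' @param stream a [sensor_stream].
#' @param target_hz target sampling rate in Hz.
#' @param t_start,t_end optional time range of the output grid (defaults to
#'   the stream's own span).
#' @return A [sensor_stream] on a uniform `target_hz` grid.
#' @export
resample_stream <- function(stream, target_hz, t_start = NULL, t_end = NULL) {
  stopifnot(target_hz > 0)
  tt <- stream_time(stream)
  if (is.null(t_start)) t_start <- tt[1]
  if (is.null(t_end)) t_end <- tt[length(tt)]
  tnew <- seq(t_start, t_end, by = 1 / target_hz)
  vals <- apply(stream$values, 2, function(col)
    approx(tt, col, xout = tnew, rule = 2)$y)
  sensor_stream(vals, target_hz, stream$channels, t0_s = tnew[1])
}

#' Differentiate a uniformly sampled channel
#'
#' Central finite differences with one-sided differences at the edges;
#' optionally low-pass filters the signal first (zero-phase Butterworth) so
#' that measurement noise is not amplified by differencing.
#'
#' @param x numeric vector.
#' @param sample_rate_hz sampling rate in Hz.
#' @param smooth_hz optional low-pass cutoff applied before differencing
#'   (`NULL` = no smoothing).
#' @return Derivative of `x`, same length.
#' @export
differentiate <- function(x, sample_rate_hz, smooth_hz = NULL) {
  if (!is.null(smooth_hz)) x <- lowpass(x, sample_rate_hz, smooth_hz)
  n <- length(x)
  d <- numeric(n)
  d[1] <- (x[2] - x[1]) * sample_rate_hz
  d[n] <- (x[n] - x[n - 1]) * sample_rate_hz
  if (n > 2) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * sample_rate_hz / 2
  d
}

# Local maxima with prominence and spacing constraints. Returns 1-based
# indices. Prominence: height above the higher of the two bracketing valleys.
find_peaks <- function(x, min_prominence, min_spacing) {
  n <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- x[1:i]; right <- x[i:n]
    higher_l <- which(left > x[i])
    base_l <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    higher_r <- which(right > x[i])
    base_r <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    x[i] - max(base_l, base_r)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce spacing greedily, tallest first
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) if (!length(sel) || all(abs(sel - i) >= min_spacing))
    sel <- c(sel, i)
  sort(sel)
}

#' Segment a session into finish-to-finish rowing cycles
#'
#' Finish events are local maxima of the reference channel (starboard oar
#' angle on the boat, handle position on the ergometer); the catch is the
#' minimum between consecutive finishes. Peaks must have prominence of at
#' least 20% of the channel range and be spaced at least 60/50 s apart
#' (50 spm is taken as the fastest plausible stroke rate). Cycles with
#' duration outside `[min_cycle_s, max_cycle_s]` are discarded.
#'
#' @param reference numeric vector (handle position or starboard oar angle).
#' @param sample_rate_hz sampling rate in Hz.
#' @param min_cycle_s,max_cycle_s admissible cycle duration bounds, s.
#' @param subject_id identifier stored in the emitted cycles.
#' @return List of [rowing_cycle] objects (possibly empty).
#' @export
segment_cycles <- function(reference, sample_rate_hz, min_cycle_s = 1,
                           max_cycle_s = 5, subject_id = "s") {
  rng <- diff(range(reference))
  if (rng == 0) return(list())
  finishes <- find_peaks(reference, min_prominence = 0.2 * rng,
                         min_spacing = (60 / 50) * sample_rate_hz)
  if (length(finishes) < 2) return(list())
  cycles <- list()
  for (k in seq_len(length(finishes) - 1)) {
    i0 <- finishes[k]; i1 <- finishes[k + 1]
    dur <- (i1 - i0) / sample_rate_hz
    if (dur < min_cycle_s || dur > max_cycle_s) next
    seg <- reference[i0:i1]
    catch <- i0 + which.min(seg) - 1
    if (catch <= i0 || catch >= i1) next
    cycles[[length(cycles) + 1]] <- rowing_cycle(
      subject_id, start_idx = i0 - 1, end_idx = i1 - 1, catch_idx = catch - 1,
      stroke_rate_spm = 60 / dur)
  }
  cycles
}

#' Detect the effective drive phase inside one cycle
#'
#' The effective drive phase begins at the first sample where the handle or
#' gate force exceeds `on_N` (20 kgf = 196.2 N) and ends at the first later
#' sample where it drops below `off_N` (10 kgf = 98.1 N), half-open
#' `[drive_start, drive_end)`, 0-based within the cycle.
#'
#' @param force numeric vector, one cycle's handle/gate force in N.
#' @param on_N onset threshold in N.
#' @param off_N offset threshold in N.
#' @return List with 0-based `drive_start_idx`, `drive_end_idx`, and
#'   `complete` (`FALSE` when the force never fell below `off_N`, in which
#'   case the drive runs to the cycle end and a warning is raised).
#' @export
detect_drive_phase <- function(force, on_N = 196.2, off_N = 98.1) {
  on <- which(force > on_N)
  if (!length(on)) stop("no_drive_detected")
  start <- on[1]
  after <- which(force[start:length(force)] < off_N)
  if (length(after)) {
    end <- start + after[1] - 1  # first sample below off_N, exclusive bound
    complete <- TRUE
  } else {
    end <- length(force) + 1
    complete <- FALSE
    warning("drive phase did not terminate before cycle end")
  }
  list(drive_start_idx = start - 1, drive_end_idx = end - 1, complete = complete)
}

# Drop cycles containing NaN or extreme-z samples in any required channel.
drop_artifact_cycles <- function(cycles, channels, zmax = 6) {
  stats_z <- lapply(channels, function(x) {
    mu <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mu) / s
  })
  Filter(function(cy) {
    ok <- vapply(seq_along(channels), function(j) {
      seg <- cycle_slice(channels[[j]], cy)
      zseg <- cycle_slice(stats_z[[j]], cy)
      !anyNA(seg) && all(abs(zseg) <= zmax)
    }, logical(1))
    all(ok)
  }, cycles)
}
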