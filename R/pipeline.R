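# End-to-end orchestration: simulate -> preprocess/segment -> targets ->
# features -> train -> evaluate, with deterministic seeding throughout.

#' Simulate a cohort of rowing sessions
#'
#' Subjects (profile + technique) are drawn from the cohort sampler; each
#' session's randomness flows from one per-subject seed derived from
#' `seed`.
#'
#' @param condition `"ergometer"` or `"boat"`.
#' @param n_subjects number of subjects.
#' @param n_cycles complete cycles per subject session.
#' @param seed master seed.
#' @param noise_sd noise multiplier passed to every subject's parameters.
#' @param ... further arguments to the session simulator.
#' @return List of session objects (`streams`, `truth`, `profile`, `params`).
#' @export
simulate_cohort <- function(condition, n_subjects, n_cycles, seed = 1,
                            noise_sd = 1, ...) {
  seeds <- with_seed(seed, sample.int(1e8, n_subjects))
  lapply(seq_len(n_subjects), function(i) {
    su <- sample_subject(condition, seeds[i])
    su$params$noise_sd <- noise_sd
    if (condition == "ergometer")
      simulate_ergo_session(su$profile, su$params, n_cycles, ...)
    else
      simulate_boat_session(su$profile, su$params, n_cycles, ...)
  })
}

# segment + annotate + artifact-drop the cycles of one session
session_cycles <- function(session, condition) {
  streams <- session$streams
  if (condition == "ergometer") {
    st <- streams$sensors
    fs <- st$sample_rate_hz
    ref <- stream_channel(st, "X_handle")
    force <- stream_channel(st, "F_handle")
    chans <- lapply(st$channels, function(ch) stream_channel(st, ch))
  } else {
    fs <- streams$oars$sample_rate_hz
    ref <- stream_channel(streams$oars, "theta_starboard")
    force <- stream_channel(streams$oars, "Fg_x_port") +
      stream_channel(streams$oars, "Fg_x_starboard")
    chans <- unlist(lapply(streams, function(s)
      lapply(s$channels, function(ch) stream_channel(s, ch))), recursive = FALSE)
  }
  cycles <- segment_cycles(ref, fs, min_cycle_s = 1, max_cycle_s = 5,
                           subject_id = session$profile$subject_id)
  cycles <- drop_artifact_cycles(cycles, chans, zmax = 6)
  annotate_cycles(cycles, force, fs)
}

#' Build per-cycle training records for one session
#'
#' Runs segmentation, drive-phase annotation, target assembly, and feature
#' assembly, returning one record per usable cycle (the first cycle has no
#' previous-stroke scalars and is dropped). Each record holds the raw
#' feature matrix `x` (`T x nI`), target matrix `y` (`T x 6`), the subject
#' id, and the cycle-relative catch/drive indices used by evaluation.
#'
#' @param session a simulated or loaded session.
#' @param condition `"ergometer"` or `"boat"`.
#' @param smooth_hz low-pass cutoff used before numerical differentiation.
#' @param li inner lever length (boat), m.
#' @return List of cycle records.
#' @export
prepare_session_records <- function(session, condition, smooth_hz = 10,
                                    li = 0.88) {
  streams <- session$streams
  profile <- session$profile
  cycles <- session_cycles(session, condition)
  if (length(cycles) < 2) return(list())
  targets <- build_targets(streams, cycles, condition, li = li,
                           smooth_hz = smooth_hz)
  stopifnot(length(targets) == length(cycles))
  if (condition == "ergometer") {
    st <- streams$sensors
    fs <- st$sample_rate_hz
    kin <- ergo_segment_kinematics(stream_channel(st, "X_handle"),
                                   stream_channel(st, "X_chest"),
                                   stream_channel(st, "X_seat"), fs,
                                   smooth_hz = smooth_hz)
    feat <- function(k) build_ergo_features(cycles[[k]], cycles[[k - 1]],
                                            kin, profile, fs)
  } else {
    chans <- prepare_boat_channels(streams, smooth_hz = smooth_hz)
    feat <- function(k) build_boat_features(cycles[[k]], cycles[[k - 1]],
                                            chans, profile)
  }
  records <- list()
  for (k in 2:length(cycles)) {
    cy <- cycles[[k]]
    x <- feat(k)
    assert_no_force_features(colnames(x))
    y <- do.call(cbind, targets[[k]][.rk_target_names])
    records[[length(records) + 1]] <- list(
      x = x, y = y, subject_id = cy$subject_id,
      catch_rel = cy$catch_idx - cy$start_idx,
      drive_rel = c(cy$drive_start_idx - cy$start_idx,
                    cy$drive_end_idx - cy$start_idx),
      stroke_rate_spm = cy$stroke_rate_spm)
  }
  records
}

#' Build the full per-cycle dataset for a cohort of sessions
#'
#' @param sessions list of sessions (e.g. from [simulate_cohort()]).
#' @inheritParams prepare_session_records
#' @return List of cycle records pooled over sessions.
#' @export
prepare_dataset <- function(sessions, condition, smooth_hz = 10, li = 0.88) {
  unlist(lapply(sessions, prepare_session_records, condition = condition,
                smooth_hz = smooth_hz, li = li), recursive = FALSE)
}

#' Synchronize a boat session's GPS stream to the IMU clock
#'
#' Integrates the boat accelerometer to velocity (drift-removed), high-pass
#' filters the GPS velocity identically, estimates the lag by normalized
#' cross-correlation, and resamples the GPS channel onto the IMU clock.
#'
#' @param session a boat session.
#' @param max_lag_s maximum |lag| searched, s.
#' @return The session with corrected GPS stream; the `sync_result` is
#'   attached as attribute `"sync"`.
#' @export
sync_boat_session <- function(session, max_lag_s = 5) {
  streams <- session$streams
  fs <- streams$gps$sample_rate_hz
  imu_v <- integrate_and_highpass(stream_channel(streams$boat_imu, "A_boat"), fs)
  gps_hp <- highpass(stream_channel(streams$gps, "V_boat"), fs)
  sy <- synchronize(gps_hp, imu_v, fs, max_lag_s = max_lag_s)
  v <- stream_channel(streams$gps, "V_boat")
  tt <- stream_time(streams$gps)
  corrected <- approx(tt, v, xout = tt + sy$lag_s, rule = 2)$y
  session$streams$gps$values[, "V_boat"] <- corrected
  attr(session, "sync") <- sy
  session
}

#' Run the full estimation pipeline on synthetic data
#'
#' Simulates a cohort, builds targets and features, trains the LSTM on a
#' stratified 80/20 cycle split, evaluates drive-phase errors and technique
#' determinants, and (optionally) runs leave-one-subject-out validation.
#' All randomness derives from `seed`.
#'
#' @param condition `"ergometer"` or `"boat"`.
#' @param n_subjects,n_cycles cohort size.
#' @param seed master seed.
#' @param lstm_units,dropout network hyperparameters.
#' @param tcfg a [train_config].
#' @param run_loov also run leave-one-subject-out validation.
#' @param out_dir optional directory for the JSON report.
#' @param noise_sd generator noise multiplier.
#' @return List of class `rk_report`: split metrics, determinant
#'   accuracies, optional LOOV aggregate, and configuration.
#' @export
run_pipeline <- function(condition = "ergometer", n_subjects = 12,
                         n_cycles = 80, seed = 1, lstm_units = 64,
                         dropout = 0, tcfg = train_config(seed = seed),
                         run_loov = FALSE, out_dir = NULL, noise_sd = 1) {
  sessions <- simulate_cohort(condition, n_subjects, n_cycles, seed,
                              noise_sd = noise_sd)
  records <- prepare_dataset(sessions, condition)
  nI <- ncol(records[[1]]$x)
  cfg <- network_config(nI, lstm_units, dropout, seed = seed)
  sp <- split_records(records, 0.8, seed)
  model <- train_network(build_network(cfg), records[sp$train],
                         records[sp$val], tcfg)
  val <- records[sp$val]
  preds <- predict_cycles(model, val)
  split_metrics <- evaluate_predictions(val, preds)
  det_acc <- determinant_accuracy(val, preds)
  report <- list(condition = condition, seed = seed,
                 n_subjects = n_subjects, n_cycles = n_cycles,
                 n_records = length(records),
                 config = list(lstm_units = lstm_units, dropout = dropout,
                               max_epochs = tcfg$max_epochs,
                               learning_rate = tcfg$learning_rate,
                               minibatch = tcfg$minibatch,
                               patience = tcfg$patience_epochs),
                 best_epoch = model$history$best_epoch,
                 split_metrics = split_metrics,
                 determinant_accuracy = det_acc)
  if (run_loov) {
    lo <- leave_one_out(records, cfg, tcfg)
    report$loov_metrics <- lo$aggregate
  }
  class(report) <- "rk_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Intra-/inter-subject determinant accuracies for a validation set
#'
#' Computes As and Ap for every (target, determinant) combination from the
#' segment-power sequences, following the convention of evaluating
#' technique on the arms/trunk/legs powers.
#'
#' @param records validation cycle records.
#' @param preds predictions from [predict_cycles()].
#' @param targets targets to evaluate determinants on.
#' @return Data frame with columns target, determinant, As, Ap.
#' @export
determinant_accuracy <- function(records, preds,
                                 targets = c("Pa", "Pt", "Pl")) {
  ys <- lapply(records, `[[`, "y")
  rows <- list()
  for (tg in targets) for (dt in c("T2P", "M2P", "WR")) {
    dm <- determinants_by_subject(records, ys, tg, dt)
    de <- determinants_by_subject(records, preds, tg, dt)
    As <- tryCatch(intra_subject_accuracy(dm, de)$As, error = function(e) NA)
    Ap <- tryCatch(inter_subject_accuracy(dm, de)$Ap, error = function(e) NA)
    rows[[length(rows) + 1]] <- data.frame(target = tg, determinant = dt,
                                           As = As, Ap = Ap)
  }
  do.call(rbind, rows)
}

#' @export
print.rk_report <- function(x, ...) {
  cat(sprintf("<rk_report> %s | %d subjects x %d cycles | seed %d\n",
              x$condition, x$n_subjects, x$n_cycles, x$seed))
  cat(sprintf("  80/20 split: mean MAE_norm %.2f%%, mean cMAE_norm %.2f%%\n",
              mean(x$split_metrics$MAE_norm), mean(x$split_metrics$cMAE_norm)))
  if (!is.null(x$loov_metrics))
    cat(sprintf("  LOOV:        mean MAE_norm %.2f%%\n",
                mean(x$loov_metrics$MAE_norm)))
  cat(sprintf("  mean Ap %.1f%%, mean As %.1f%%\n",
              mean(x$determinant_accuracy$Ap, na.rm = TRUE),
              mean(x$determinant_accuracy$As, na.rm = TRUE)))
  invisible(x)
}
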