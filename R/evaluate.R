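# Performance metrics: drive-phase MAE / cycle-averaged MAE (raw and
# normalized), technique determinants (T2P, M2P, WR), and t-test based
# intra-/inter-subject technique discrimination accuracy.

#' Interpolate a drive-phase slice onto the 50-frame grid
#'
#' Cycles have different durations; metric computation compares sequences
#' linearly interpolated onto 50 equally spaced frames spanning the
#' effective drive phase.
#'
#' @param x numeric vector (the drive-phase slice, >= 2 samples).
#' @param n_frames number of frames.
#' @return Numeric vector of length `n_frames`.
#' @export
interp_drive_grid <- function(x, n_frames = 50) {
  if (length(x) < 2) stop("drive window has fewer than 2 samples")
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_frames))$y
}

#' Mean absolute error and cycle-averaged MAE over the drive grid
#'
#' `MAE` averages |error| over all cycles and frames; `cMAE` first averages
#' the residual over cycles frame-by-frame and then takes the mean absolute
#' value, i.e. the error of the cycle-averaged curve. `cMAE <= MAE` always.
#'
#' @param measured,estimated numeric matrices, `C cycles x T frames`.
#' @return List with `MAE` and `cMAE`.
#' @export
mae_cmae <- function(measured, estimated) {
  measured <- rbind(measured); estimated <- rbind(estimated)
  C <- nrow(measured)
  if (C == 0) stop("no cycles")
  stopifnot(all(dim(measured) == dim(estimated)))
  resid <- measured - estimated
  list(MAE = mean(abs(resid)),
       cMAE = sum(abs(colSums(resid))) / (C * ncol(measured)))
}

#' Express an error as a percentage of the mean measured curve
#'
#' @param err error in original units (N or W).
#' @param measured measured drive-grid curves (matrix or vector) defining
#'   the normalizer `mean(V)`.
#' @return `100 * err / mean(measured)`.
#' @export
normalize_error <- function(err, measured) {
  v <- mean(measured)
  if (abs(v) < 1e-9) stop("degenerate_normalizer")
  100 * err / v
}

#' Technique determinants of one curve
#'
#' Over the catch-to-finish drive window: `T2P` is the peak instant in
#' percent of the window; `M2P` is 100 * mean/max; `WR` is 100 * (area
#' under the curve before the peak) / (total area), trapezoidal. Plateau
#' peaks resolve to the first index of the maximum.
#'
#' @param x numeric vector, the curve over the entire drive phase.
#' @return List with `T2P`, `M2P`, `WR` (percent).
#' @export
determinants <- function(x) {
  if (all(x == 0)) stop("no_peak")
  k <- which.max(x)
  T2P <- 100 * (k - 1) / (length(x) - 1)
  M2P <- 100 * mean(x) / max(x)
  total <- pracma::trapz(seq_along(x), x)
  before <- if (k == 1) 0 else pracma::trapz(1:k, x[1:k])
  WR <- 100 * before / total
  list(T2P = T2P, M2P = M2P, WR = WR)
}

# two-sample t-test decision at alpha; pooled variance by default
ttest_reject <- function(a, b, alpha = 0.05, var_equal = TRUE) {
  t.test(a, b, var.equal = var_equal)$p.value <= alpha
}

#' Intra-subject technique accuracy
#'
#' Per subject, a two-sample t-test compares the determinant computed from
#' measured cycles against the same determinant from estimated cycles; the
#' accuracy is the percentage of subjects where the null hypothesis of
#' equal means is retained (p > alpha).
#'
#' @param measured,estimated named lists (by subject) of per-cycle
#'   determinant values.
#' @param alpha significance level.
#' @param var_equal pooled-variance t-test (Welch when `FALSE`).
#' @return List with `As` (percent) and the per-subject rejection vector.
#' @export
intra_subject_accuracy <- function(measured, estimated, alpha = 0.05,
                                   var_equal = TRUE) {
  subjects <- names(measured)
  keep <- vapply(subjects, function(s)
    length(measured[[s]]) >= 2 && length(estimated[[s]]) >= 2, logical(1))
  if (any(!keep)) warning("subjects with < 2 cycles excluded: ",
                          paste(subjects[!keep], collapse = ", "))
  subjects <- subjects[keep]
  rej <- vapply(subjects, function(s)
    ttest_reject(measured[[s]], estimated[[s]], alpha, var_equal), logical(1))
  list(As = 100 * sum(!rej) / length(rej), rejected = rej)
}

#' Inter-subject technique discrimination accuracy
#'
#' For every unordered subject pair, the equal-means t-test decision is
#' computed once on the measured determinants and once on the estimated
#' determinants; the accuracy is the percentage of pairs where the two
#' decisions agree.
#'
#' @inheritParams intra_subject_accuracy
#' @return List with `Ap` (percent) and the pairwise agreement matrix.
#' @export
inter_subject_accuracy <- function(measured, estimated, alpha = 0.05,
                                   var_equal = TRUE) {
  subjects <- names(measured)
  keep <- vapply(subjects, function(s)
    length(measured[[s]]) >= 2 && length(estimated[[s]]) >= 2, logical(1))
  subjects <- subjects[keep]
  if (length(subjects) < 2) stop("need >= 2 subjects with >= 2 cycles")
  n <- length(subjects)
  agree <- matrix(NA, n, n, dimnames = list(subjects, subjects))
  ch <- dh <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    rm_ <- ttest_reject(measured[[subjects[i]]], measured[[subjects[j]]],
                        alpha, var_equal)
    re_ <- ttest_reject(estimated[[subjects[i]]], estimated[[subjects[j]]],
                        alpha, var_equal)
    agree[i, j] <- agree[j, i] <- (rm_ == re_)
    if (rm_ == re_) ch <- ch + 1 else dh <- dh + 1
  }
  list(Ap = 100 * ch / (ch + dh), agreement = agree)
}

# 50-frame drive-grid matrices (C x 50) for one target across records
drive_grid_matrix <- function(records, seqs, target, n_frames = 50) {
  do.call(rbind, lapply(seq_along(records), function(i) {
    r <- records[[i]]
    win <- (r$drive_rel[1] + 1):r$drive_rel[2]
    interp_drive_grid(seqs[[i]][win, target], n_frames)
  }))
}

#' Per-target evaluation table for a validation set
#'
#' Interpolates measured and estimated sequences onto the 50-frame
#' effective-drive grid (the window detected from the measured handle/gate
#' force) and reports `MAE`, `cMAE`, and their normalized versions per
#' target.
#'
#' @param records list of cycle records (with `y` and `drive_rel`).
#' @param preds list of predicted `T x 6` matrices from [predict_cycles()].
#' @param n_frames drive-grid length.
#' @return Data frame with one row per target: `MAE`, `cMAE`, `MAE_norm`,
#'   `cMAE_norm`.
#' @export
evaluate_predictions <- function(records, preds, n_frames = 50) {
  ys <- lapply(records, `[[`, "y")
  tabs <- lapply(.rk_target_names, function(tg) {
    M <- drive_grid_matrix(records, ys, tg, n_frames)
    E <- drive_grid_matrix(records, preds, tg, n_frames)
    e <- mae_cmae(M, E)
    data.frame(target = tg, MAE = e$MAE, cMAE = e$cMAE,
               MAE_norm = normalize_error(e$MAE, M),
               cMAE_norm = normalize_error(e$cMAE, M))
  })
  do.call(rbind, tabs)
}

#' Per-cycle technique determinants grouped by subject
#'
#' Determinants are computed over the entire catch-to-finish drive window
#' of each cycle (not the threshold-based effective drive phase).
#'
#' @param records list of cycle records.
#' @param seqs list of `T x 6` sequences (measured `y` or predictions).
#' @param target one of the six target names.
#' @param determinant `"T2P"`, `"M2P"`, or `"WR"`.
#' @return Named list (by subject) of per-cycle determinant values.
#' @export
determinants_by_subject <- function(records, seqs, target,
                                    determinant = "T2P") {
  subj <- vapply(records, `[[`, "", "subject_id")
  vals <- vapply(seq_along(records), function(i) {
    r <- records[[i]]
    win <- (r$catch_rel + 1):nrow(seqs[[i]])
    determinants(seqs[[i]][win, target])[[determinant]]
  }, numeric(1))
  split(vals, subj)
}
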