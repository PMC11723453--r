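# Sequence-to-sequence LSTM regressor: configuration, training, random
# hyperparameter search, and leave-one-subject-out validation.

#' Network configuration
#'
#' The layer stack is: sequence input (nI) -> fully connected (nI) -> LSTM
#' (lstm_units) -> dropout -> fully connected (nO) -> per-timestep squared
#' error regression.
#'
#' @param nI number of input channels (16 ergometer / 18 boat).
#' @param lstm_units LSTM hidden units, in [10, 500].
#' @param dropout dropout fraction, one of 0, 0.05, 0.10.
#' @param nO number of output channels (6 targets).
#' @param seed weight-initialization seed.
#' @return Object of class `network_config`.
#' @export
network_config <- function(nI, lstm_units, dropout = 0, nO = 6, seed = 1) {
  stopifnot(nO == 6, lstm_units >= 10, lstm_units <= 500,
            dropout %in% c(0, 0.05, 0.10))
  if (!nI %in% c(16, 18))
    warning("nI = ", nI, " does not match a standard condition (16/18)")
  structure(list(nI = as.integer(nI), nO = as.integer(nO),
                 lstm_units = as.integer(lstm_units), dropout = dropout,
                 seed = as.integer(seed)), class = "network_config")
}

#' Training configuration
#'
#' Defaults follow standard practice for this task: Adam, learning rate
#' 0.001, minibatch 32, up to 10000 epochs with early stopping once 20
#' epochs elapse without improvement of the validation full-cycle RMSE.
#'
#' @param max_epochs maximum training epochs.
#' @param learning_rate Adam learning rate.
#' @param minibatch minibatch size (padded + loss-masked).
#' @param patience_epochs early-stopping patience.
#' @param seed seed for batch shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(max_epochs = 10000, learning_rate = 0.001,
                         minibatch = 32, patience_epochs = 20, seed = 1) {
  stopifnot(patience_epochs < max_epochs)
  structure(list(max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 minibatch = as.integer(minibatch),
                 patience_epochs = as.integer(patience_epochs),
                 seed = as.integer(seed)), class = "train_config")
}

#' Closed-form LSTM layer parameter count
#'
#' `4 * ((nI + units) * units + units)` — input, recurrent, and bias
#' parameters for the four gates.
#'
#' @param nI input width of the LSTM layer.
#' @param units hidden units.
#' @return Integer parameter count.
#' @export
lstm_param_count <- function(nI, units) 4 * ((nI + units) * units + units)

#' Build an untrained network
#'
#' @param cfg a [network_config].
#' @return Object of class `rk_model` with Glorot-initialized weights.
#' @export
build_network <- function(cfg) {
  w <- lstm_init_cpp(cfg$nI, cfg$nO, cfg$lstm_units, cfg$seed)
  structure(list(weights = w, config = cfg, norm = NULL, history = NULL),
            class = "rk_model")
}

#' @export
print.rk_model <- function(x, ...) {
  cat(sprintf("<rk_model> nI=%d units=%d dropout=%g%s\n", x$config$nI,
              x$config$lstm_units, x$config$dropout,
              if (is.null(x$history)) " (untrained)" else
                sprintf(" | best val RMSE %.4f @ epoch %d",
                        x$history$best_val_rmse, x$history$best_epoch)))
  invisible(x)
}

# records -> normalized, transposed (channels x T) matrices for the C++ core
records_to_xy <- function(records, norm) {
  list(x = lapply(records, function(r) t(apply_norm(r$x, norm$x))),
       y = lapply(records, function(r) t(apply_norm(r$y, norm$y))))
}

#' Fit input/target normalization on a set of training records
#' @param records list of cycle records (elements `x`, `y`).
#' @return List with `norm_stats` for `x` and `y`.
#' @export
fit_record_norm <- function(records) {
  list(x = fit_norm(lapply(records, `[[`, "x")),
       y = fit_norm(lapply(records, `[[`, "y")))
}

#' Train the network
#'
#' Sequences are variable-length cycles in absolute time; minibatches pad
#' to the longest member and mask the loss on padded frames. Weights from
#' the epoch with the best validation full-cycle RMSE are returned.
#'
#' @param model an `rk_model` from [build_network()].
#' @param train_records,val_records lists of cycle records (`x`: `T x nI`
#'   feature matrix, `y`: `T x 6` target matrix, raw units).
#' @param tcfg a [train_config].
#' @param norm normalization as from [fit_record_norm()]; fitted on
#'   `train_records` when `NULL`.
#' @param verbose print per-epoch progress.
#' @return The trained `rk_model` (weights, norm, history).
#' @export
train_network <- function(model, train_records, val_records, tcfg = train_config(),
                          norm = NULL, verbose = FALSE) {
  if (!length(val_records)) stop("empty validation set")
  if (is.null(norm)) norm <- fit_record_norm(train_records)
  tr <- records_to_xy(train_records, norm)
  va <- records_to_xy(val_records, norm)
  fit <- lstm_train_cpp(model$weights, tr$x, tr$y, va$x, va$y,
                        tcfg$max_epochs, tcfg$learning_rate, tcfg$minibatch,
                        tcfg$patience_epochs, model$config$dropout,
                        tcfg$seed, verbose)
  model$weights <- fit$weights
  model$norm <- norm
  model$history <- list(train_loss = fit$train_loss, val_rmse = fit$val_rmse,
                        best_val_rmse = fit$best_val_rmse,
                        best_epoch = fit$best_epoch)
  model
}

#' Predict the six target sequences for cycle records
#'
#' @param model a trained `rk_model`.
#' @param records list of cycle records with `x` matrices.
#' @return List of `T x 6` predicted target matrices, de-normalized to
#'   original units (N, W).
#' @export
predict_cycles <- function(model, records) {
  stopifnot(!is.null(model$norm))
  xs <- lapply(records, function(r) t(apply_norm(r$x, model$norm$x)))
  preds <- lstm_predict_cpp(model$weights, xs)
  lapply(preds, function(p) {
    m <- invert_norm(t(p), model$norm$y)
    colnames(m) <- names(model$norm$y$mean)
    m
  })
}

#' Split cycle records into training and validation sets
#'
#' Random split by cycle, stratified by subject so every subject appears in
#' both parts (switchable to unstratified).
#'
#' @param records list of cycle records with `subject_id`.
#' @param train_frac training fraction.
#' @param seed RNG seed.
#' @param stratify stratify by subject.
#' @return List with `train` and `val` index vectors.
#' @export
split_records <- function(records, train_frac = 0.8, seed = 1, stratify = TRUE) {
  subj <- vapply(records, `[[`, "", "subject_id")
  with_seed(seed, {
    if (stratify) {
      tr <- unlist(lapply(split(seq_along(records), subj), function(ix) {
        sample(ix, max(1, round(train_frac * length(ix))))
      }), use.names = FALSE)
    } else {
      tr <- sample(seq_along(records), round(train_frac * length(records)))
    }
    list(train = sort(tr), val = setdiff(seq_along(records), tr))
  })
}

#' Sample random-search configurations
#'
#' Units are log-uniform over [10, 500] (rounded); dropout uniform over
#' {0, 0.05, 0.10}.
#'
#' @param n number of configurations.
#' @param nI input width.
#' @param seed RNG seed.
#' @return List of [network_config]s.
#' @export
sample_search_configs <- function(n, nI, seed = 1) {
  with_seed(seed, {
    units <- pmin(500, pmax(10, round(exp(runif(n, log(10), log(500))))))
    dop <- sample(c(0, 0.05, 0.10), n, replace = TRUE)
    lapply(seq_len(n), function(i)
      network_config(nI, units[i], dop[i], seed = seed + i))
  })
}

# mean drive-phase MAE across the six de-normalized targets (search objective)
drive_mae_score <- function(records, preds) {
  tab <- evaluate_predictions(records, preds)
  mean(tab$MAE)
}

#' Random hyperparameter search
#'
#' Trains each sampled configuration on an 80/20 cycle split and selects
#' the one minimizing the mean drive-phase MAE over the six de-normalized
#' targets on the validation cycles.
#'
#' @param records list of cycle records.
#' @param n_trials number of random configurations (>= 1).
#' @param nI input width.
#' @param tcfg a [train_config].
#' @param seed RNG seed (configuration sampling and split).
#' @return List with `best` ([network_config]), `best_model`, and a `trials`
#'   data frame (units, dropout, score).
#' @export
random_search <- function(records, n_trials, nI, tcfg = train_config(),
                          seed = 1) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  cfgs <- sample_search_configs(n_trials, nI, seed)
  sp <- split_records(records, 0.8, seed)
  scores <- numeric(n_trials)
  models <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    m <- train_network(build_network(cfgs[[i]]), records[sp$train],
                       records[sp$val], tcfg)
    models[[i]] <- m
    scores[i] <- drive_mae_score(records[sp$val],
                                 predict_cycles(m, records[sp$val]))
  }
  k <- which.min(scores)
  list(best = cfgs[[k]], best_model = models[[k]],
       trials = data.frame(
         units = vapply(cfgs, `[[`, 0L, "lstm_units"),
         dropout = vapply(cfgs, `[[`, 0, "dropout"),
         score = scores))
}

#' Leave-one-subject-out validation
#'
#' For each of the N subjects, trains on the other N-1 subjects' cycles and
#' validates on the held-out subject; metrics are aggregated as the mean
#' over subjects. Subjects with no cycles are skipped with a warning.
#'
#' @param records list of cycle records.
#' @param cfg a [network_config].
#' @param tcfg a [train_config].
#' @param verbose print fold progress.
#' @return List with `folds` (per-subject: subject, model, metric table) and
#'   `aggregate` (mean metric table over subjects).
#' @export
leave_one_out <- function(records, cfg, tcfg = train_config(), verbose = FALSE) {
  subj <- vapply(records, `[[`, "", "subject_id")
  subjects <- unique(subj)
  if (length(subjects) < 3) stop("leave-one-out needs >= 3 subjects")
  folds <- list()
  for (s in subjects) {
    val_ix <- which(subj == s)
    if (!length(val_ix)) {
      warning("subject ", s, " has no cycles; fold skipped")
      next
    }
    m <- train_network(build_network(cfg), records[-val_ix],
                       records[val_ix], tcfg)
    preds <- predict_cycles(m, records[val_ix])
    tab <- evaluate_predictions(records[val_ix], preds)
    if (verbose) message("fold ", s, ": mean MAE_norm ",
                         round(mean(tab$MAE_norm), 2), "%")
    folds[[s]] <- list(subject = s, model = m, metrics = tab, preds = preds,
                       val_ix = val_ix)
  }
  mats <- lapply(folds, function(f) as.matrix(f$metrics[, -1]))
  agg <- Reduce(`+`, mats) / length(mats)
  aggregate <- data.frame(target = folds[[1]]$metrics$target, agg,
                          check.names = FALSE)
  list(folds = folds, aggregate = aggregate)
}
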